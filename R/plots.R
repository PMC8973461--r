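#' Plot fitted parameter maps
#'
#' Raster display of one or more fitted maps, faceted by parameter.
#'
#' @param object A [fit_sir()] result.
#' @param parameters Which maps to show (default the free parameters).
#' @param slice Which slice of the 3rd dimension (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sir_fit <- function(object, parameters = object$free, slice = 1L,
                             ...) {
  df <- tidy(object, mask_only = FALSE)
  df <- df[df$z == slice, c("x", "y", parameters)]
  long <- tidyr_pivot(df, parameters)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$y, y = .data$x,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row", fill = NULL,
                  title = "Fitted SIR parameter maps")
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_pivot <- function(df, cols) {
  purrr::map_dfr(cols, function(nm) {
    tibble::tibble(x = df$x, y = df$y, parameter = nm, value = df[[nm]])
  })
}

#' Plot phantom truth grids
#'
#' @param object A [sir_phantom()].
#' @param ... Unused.
#' @return A ggplot object with PSR and R1f truth maps side by side.
#' @export
autoplot.sir_phantom <- function(object, ...) {
  long <- purrr::map_dfr(c("psr", "r1f"), function(nm) {
    tibble::tibble(row = object$row, col = object$col,
                   parameter = nm, value = object[[nm]])
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~parameter) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row", fill = NULL,
                  title = "Phantom ground truth")
}

#' Plot a percent-difference density histogram
#'
#' @param object A [percent_difference_histogram()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sir_pdhist <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_col(width = object$upper - object$lower,
                      fill = "steelblue", colour = "grey30") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "percent difference (estimate vs truth)",
                  y = "probability density")
}

#' Concordance scatter of estimates against truth
#'
#' Truth-versus-estimate scatter with the identity line, annotated with
#' Lin's concordance correlation coefficient.
#'
#' @param truth,estimate Equal-length numeric vectors.
#' @param label Axis/annotation label for the parameter.
#' @return A ggplot object.
#' @export
plot_concordance <- function(truth, estimate, label = "parameter") {
  cc <- lccc(truth, estimate)
  df <- tibble::tibble(truth = truth, estimate = estimate)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$estimate)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = sprintf("true %s", label),
                  y = sprintf("fitted %s", label),
                  subtitle = sprintf("LCCC = %.3f (n = %d)", cc$lccc, cc$n))
}
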