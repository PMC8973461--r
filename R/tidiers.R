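#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a voxelwise SIR fit into one row per voxel
#'
#' @param x A [fit_sir()] result.
#' @param mask_only Keep only mask-true voxels (default `TRUE`).
#' @param ... Unused.
#' @return Tibble with voxel indices (`x`, `y`, `z`), the fitted parameter
#'   columns, and diagnostics (`residual_norm`, `iterations`, `converged`).
#' @export
tidy.sir_fit <- function(x, mask_only = TRUE, ...) {
  dims <- dim(x$maps$psr)
  ijk <- arrayInd(seq_len(prod(dims)), dims)
  out <- tibble::tibble(x = ijk[, 1], y = ijk[, 2], z = ijk[, 3])
  for (nm in c(x$free, "residual_norm", "iterations", "converged")) {
    out[[nm]] <- as.vector(x$maps[[nm]])
  }
  if (mask_only) out <- out[as.vector(x$mask), ]
  out
}

#' One-row summary of a voxelwise SIR fit
#'
#' @param x A [fit_sir()] result.
#' @param ... Unused.
#' @return Tibble: voxel counts, convergence rate, iteration and residual
#'   summaries, elapsed wall time.
#' @export
glance.sir_fit <- function(x, ...) {
  conv <- x$maps$converged[x$mask]
  tibble::tibble(
    n_voxels = prod(dim(x$maps$psr)),
    n_fitted = x$n_fitted,
    n_converged = sum(conv),
    convergence_rate = mean(conv),
    median_iterations = stats::median(x$maps$iterations[x$mask]),
    median_residual_norm = stats::median(x$maps$residual_norm[x$mask]),
    elapsed_s = x$elapsed)
}
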