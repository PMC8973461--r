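#' Lin's concordance correlation coefficient
#'
#' Agreement of two measurement series with the identity line,
#' \deqn{\rho_c = \frac{2\,\mathrm{cov}(x,y)}{\sigma_x^2 + \sigma_y^2 + (\mu_x - \mu_y)^2},}
#' using population (1/n) moments — the standard Lin estimator, matching the
#' epidemiological-package convention. Decomposes as Pearson correlation
#' (precision) times a bias-correction factor (accuracy), so `|lccc| <=
#' |pearson_r|` always.
#'
#' @param x,y Equal-length finite numeric vectors (`n >= 2`), at least one
#'   with nonzero variance.
#' @return One-row tibble: `lccc`, `pearson_r`, `bias_correction`, `n`.
#' @examples
#' lccc(1:4, 1:4 + 10)
#' @export
lccc <- function(x, y) {
  if (length(x) != length(y)) {
    stop(sprintf("`x` (length %d) and `y` (length %d) must match",
                 length(x), length(y)), call. = FALSE)
  }
  n <- length(x)
  if (n < 2L || !all(is.finite(x)) || !all(is.finite(y))) {
    stop("`x` and `y` must be finite with n >= 2", call. = FALSE)
  }
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) {
    stop("degenerate input: both vectors constant with equal means (0/0)",
         call. = FALSE)
  }
  rho_c <- 2 * cxy / denom
  r <- if (vx > 0 && vy > 0) cxy / sqrt(vx * vy) else NA_real_
  cb <- if (isTRUE(r != 0)) rho_c / r else NA_real_
  tibble::tibble(lccc = rho_c, pearson_r = r, bias_correction = cb, n = n)
}

#' Relative root-mean-square error, in percent
#'
#' \eqn{100 \sqrt{\mathrm{mean}(((est - truth)/truth)^2)}}: each voxel's error
#' is taken relative to its own true value, so parameters with different
#' native units (s^-1, dimensionless ratios) are summarized on a common
#' percent scale. Invariant to common positive rescaling of both inputs.
#'
#' @param truth True values (all nonzero).
#' @param estimate Estimated values, same length.
#' @return Scalar percentage.
#' @export
rmse_percent <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    stop("`truth` and `estimate` lengths differ", call. = FALSE)
  }
  if (any(truth == 0)) {
    stop("relative error undefined: `truth` contains zeros", call. = FALSE)
  }
  100 * sqrt(mean(((estimate - truth) / truth)^2))
}

#' Percent-difference density histogram
#'
#' Histogram of `100 * (estimate - truth) / truth` normalized to unit area
#' (densities times bin widths sum to 1), the accuracy display used alongside
#' concordance analysis.
#'
#' @inheritParams rmse_percent
#' @param bins Suggested number of bins.
#' @return Tibble of class `sir_pdhist`: `lower`, `upper`, `mid`, `density`,
#'   `count` per bin, with the raw percent differences in attribute `pdiff`.
#' @export
percent_difference_histogram <- function(truth, estimate, bins = 50) {
  if (length(truth) != length(estimate)) {
    stop("`truth` and `estimate` lengths differ", call. = FALSE)
  }
  if (any(truth == 0)) {
    stop("relative difference undefined: `truth` contains zeros", call. = FALSE)
  }
  pd <- 100 * (estimate - truth) / truth
  h <- graphics::hist(pd, breaks = bins, plot = FALSE)
  structure(
    tibble::tibble(lower = utils::head(h$breaks, -1), upper = h$breaks[-1],
                   mid = h$mids, density = h$density, count = h$counts),
    pdiff = pd,
    class = c("sir_pdhist", class(tibble::tibble())))
}

#' Convert pool size ratio to macromolecular fraction
#'
#' `f = PSR / (1 + PSR)`, the fraction of total magnetization in the
#' macromolecular pool, `M0m / (M0m + M0f)`; linear in macromolecular content
#' and therefore the natural axis for phantom concentration regressions.
#' Strictly increasing, mapping `[0, Inf)` onto `[0, 1)`.
#'
#' @param psr Pool size ratio value(s), all `>= 0`.
#' @return `f`, same shape as `psr`.
#' @examples
#' psr_to_fraction(c(0, 0.25, 1))
#' @export
psr_to_fraction <- function(psr) {
  if (any(psr < 0, na.rm = TRUE)) stop("`psr` must be >= 0", call. = FALSE)
  psr / (1 + psr)
}

#' Inverse of [psr_to_fraction()]
#'
#' @param f Macromolecular fraction value(s) in `[0, 1)`.
#' @return Pool size ratio `f / (1 - f)`.
#' @export
fraction_to_psr <- function(f) {
  if (any(f < 0 | f >= 1, na.rm = TRUE)) {
    stop("`f` must lie in [0, 1)", call. = FALSE)
  }
  f / (1 - f)
}

#' Evaluate a fit against phantom ground truth
#'
#' Pairs each converged, mask-true voxel's estimate with its generating truth
#' and summarizes agreement per parameter: Lin's concordance, Pearson
#' correlation and relative RMSE. Non-converged or masked-out voxels are
#' excluded and counted.
#'
#' @param fit A [fit_sir()] result on a series simulated from `phantom`.
#' @param phantom The generating [sir_phantom()].
#' @param parameters Which parameters to score (default PSR and R1f).
#' @return Tibble: one row per parameter with `lccc`, `pearson_r`,
#'   `rmse_pct`, `n`, `n_excluded`.
#' @export
evaluate_sir_fit <- function(fit, phantom, parameters = c("psr", "r1f")) {
  stopifnot(inherits(fit, "sir_fit"), inherits(phantom, "sir_phantom"))
  shape <- attr(phantom, "shape")
  keep <- as.vector(fit$maps$converged) & as.vector(fit$mask)
  purrr::map_dfr(parameters, function(par) {
    truth <- phantom[[par]]
    est <- as.vector(fit$maps[[par]])
    cc <- lccc(truth[keep], est[keep])
    tibble::tibble(parameter = par,
                   lccc = cc$lccc, pearson_r = cc$pearson_r,
                   rmse_pct = rmse_percent(truth[keep], est[keep]),
                   n = sum(keep), n_excluded = sum(!keep))
  })
}
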