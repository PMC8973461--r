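#' Configuration for voxelwise SIR fitting
#'
#' Collects everything the fit needs beyond the data: which parameters are
#' fixed versus free, starting values, box constraints, optimizer tolerances
#' and threading.
#'
#' The four-parameter model (free PSR, R1f, Sf, M0f) fixes `kmf` to a
#' literature value; passing `kmf = NULL` (or `fit_kmf = TRUE`) switches to
#' the five-parameter model with `kmf` free, which requires at least five
#' scheme points. `r1m = NULL` ties R1m to R1f as a live constraint,
#' re-evaluated at every optimizer iterate, not frozen at the initial guess.
#'
#' Defaults not dictated by the model are mid-range of the biological box:
#' initial guess PSR = 0.10, R1f = 1.0 s^-1, Sf = -0.95, M0f = 1.2 x
#' max|signal| (scaled per voxel), kmf at its configured value; bounds
#' PSR in \[0, 1\], R1f in \[0.05, 10\] s^-1, Sf in \[-1.05, 1.05\] (slightly
#' beyond +/-1 so noise does not pin estimates to the physical boundary),
#' M0f in (0, 10 x max|signal|\], kmf in \[0, 100\] s^-1.
#'
#' @param kmf Macromolecular-to-free exchange rate to fix, s^-1 (`12.5` for
#'   brain, `35.0` for BSA phantoms), or `NULL` to estimate it per voxel.
#' @param fit_kmf Estimate `kmf`? Defaults to `is.null(kmf)`.
#' @param sm Macromolecular inversion efficiency held fixed (default 0.83).
#' @param r1m Fixed macromolecular relaxation rate, s^-1, or `NULL` to tie to
#'   the current R1f iterate.
#' @param magnitude Fit `|Mzf|` to magnitude data (default) or signed `Mzf`.
#' @param init Named list overriding initial guesses (`psr`, `r1f`, `sf`,
#'   `m0f`, `kmf`). `m0f = NA` means "scale from the data".
#' @param lower,upper Named lists overriding per-parameter bounds; `m0f = NA`
#'   in `upper` means 10 x max|signal|.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @param ftol,ptol Cost-change and step-size convergence tolerances; tight by
#'   default so optimizer tolerance is never the accuracy bottleneck.
#' @param threads Worker processes for [fit_sir()]. Results are identical for
#'   any thread count (voxels are independent).
#' @return An object of class `sir_fit_config`.
#' @export
sir_fit_config <- function(kmf = 12.5, fit_kmf = is.null(kmf), sm = 0.83,
                           r1m = NULL, magnitude = TRUE,
                           init = list(), lower = list(), upper = list(),
                           max_iter = 500L, ftol = 1e-10, ptol = 1e-10,
                           threads = 1L) {
  if (fit_kmf) {
    kmf_init <- if (is.null(kmf)) 12.5 else kmf
    kmf <- NULL
  } else {
    if (is.null(kmf) || !is.finite(kmf) || kmf <= 0) {
      stop("fixed-kmf mode requires `kmf` > 0", call. = FALSE)
    }
    kmf_init <- kmf
  }
  if (!is.null(r1m) && (!is.finite(r1m) || r1m <= 0)) {
    stop("fixed `r1m` must be > 0", call. = FALSE)
  }
  default_init <- list(psr = 0.10, r1f = 1.0, sf = -0.95, m0f = NA_real_,
                       kmf = kmf_init)
  default_lower <- list(psr = 0, r1f = 0.05, sf = -1.05, m0f = 1e-12, kmf = 0)
  default_upper <- list(psr = 1, r1f = 10, sf = 1.05, m0f = NA_real_, kmf = 100)
  cfg <- structure(
    list(kmf = kmf, fit_kmf = fit_kmf, sm = sm, r1m = r1m,
         magnitude = magnitude,
         init = utils::modifyList(default_init, init),
         lower = utils::modifyList(default_lower, lower),
         upper = utils::modifyList(default_upper, upper),
         max_iter = as.integer(max_iter), ftol = ftol, ptol = ptol,
         threads = as.integer(threads)),
    class = "sir_fit_config"
  )
  cfg
}

free_param_names <- function(config) {
  if (config$fit_kmf) c("psr", "r1f", "sf", "m0f", "kmf")
  else c("psr", "r1f", "sf", "m0f")
}

#' Build the residual function for the configured SIR model
#'
#' Dispatches on whether `kmf` is fixed or estimated: the fixed mode yields a
#' four-parameter residual closure (PSR, R1f, Sf, M0f) with `kmf` bound from
#' the configuration; the estimated mode yields a five-parameter closure with
#' `kmf` free, which needs at least five observations.
#'
#' @param config A [sir_fit_config()].
#' @param scheme A [sir_scheme()] tibble.
#' @param signal Observed signal vector, one value per scheme row.
#' @return A function `theta -> residuals` with attributes `free` (parameter
#'   names, defining the arity) and `model` (the model prediction function).
#' @export
dispatch_sir_model <- function(config, scheme, signal) {
  validate_scheme(scheme)
  free <- free_param_names(config)
  if (length(signal) != nrow(scheme)) {
    stop(sprintf("signal length (%d) does not match scheme length (%d)",
                 length(signal), nrow(scheme)), call. = FALSE)
  }
  if (nrow(scheme) < length(free)) {
    stop(sprintf(paste0("under-determined model: %d free parameters (%s) but ",
                        "only %d scheme points"),
         length(free), paste(free, collapse = ", "), nrow(scheme)),
         call. = FALSE)
  }
  ti <- scheme$ti
  td <- scheme$td
  sm <- config$sm
  r1m_fixed <- config$r1m
  kmf_fixed <- config$kmf
  magnitude <- config$magnitude
  fit_kmf <- config$fit_kmf
  model <- function(theta) {
    psr <- theta[1L]; r1f <- theta[2L]; sf <- theta[3L]; m0f <- theta[4L]
    kmf <- if (fit_kmf) theta[5L] else kmf_fixed
    r1m <- if (is.null(r1m_fixed)) r1f else r1m_fixed
    s <- sir_mz_core(psr, r1f, r1m, sf, sm, m0f, kmf, ti, td)
    if (magnitude) abs(s) else s
  }
  fn <- function(theta) model(theta) - signal
  attr(fn, "free") <- free
  attr(fn, "model") <- model
  fn
}

resolve_theta0 <- function(config, signal) {
  free <- free_param_names(config)
  init <- config$init
  smax <- max(abs(signal))
  if (is.na(init$m0f)) init$m0f <- 1.2 * smax
  lower <- unlist(config$lower[free])
  upper <- config$upper
  if (is.na(upper$m0f)) upper$m0f <- 10 * smax
  upper <- unlist(upper[free])
  theta0 <- unlist(init[free])
  theta0 <- pmin(pmax(theta0, lower), upper)
  list(theta0 = theta0, lower = lower, upper = upper)
}

#' Fit the SIR model to one voxel's signal
#'
#' Bounded Levenberg-Marquardt least squares of the two-pool SIR model
#' against one voxel's signal across the scheme. Non-convergence is reported
#' through the `converged` flag, never as an error; an all-zero (or
#' non-finite) signal is skipped with zero-filled estimates.
#'
#' @inheritParams dispatch_sir_model
#' @return A one-row tibble with the free parameter estimates plus
#'   `residual_norm`, `iterations`, `converged`.
#' @examples
#' sch <- sir_default_scheme()
#' y <- sir_signal(sch, sir_params(psr = 0.15, r1f = 1.0))$signal
#' fit_sir_voxel(y, sch, sir_fit_config(kmf = 12.5))
#' @export
fit_sir_voxel <- function(signal, scheme, config = sir_fit_config()) {
  fn <- dispatch_sir_model(config, scheme, signal)
  free <- attr(fn, "free")
  empty <- as.list(stats::setNames(rep(0, length(free)), free))
  if (!all(is.finite(signal)) || all(signal == 0)) {
    return(tibble::as_tibble(c(empty, list(residual_norm = 0, iterations = 0L,
                                           converged = FALSE))))
  }
  box <- resolve_theta0(config, signal)
  res <- minpack.lm::nls.lm(
    par = box$theta0, lower = box$lower, upper = box$upper, fn = fn,
    control = minpack.lm::nls.lm.control(
      ftol = config$ftol, ptol = config$ptol, maxiter = config$max_iter))
  est <- as.list(stats::setNames(as.numeric(res$par), free))
  tibble::as_tibble(c(est, list(
    residual_norm = sqrt(sum(res$fvec^2)),
    iterations = as.integer(res$niter),
    converged = res$info %in% 1:4)))
}

#' Fit the SIR model to every voxel of a 4-D series
#'
#' Runs the per-voxel fit over all mask-true voxels of a [sir_series()]. Each
#' voxel is fit independently, so the result is identical for any `threads`
#' setting or voxel visitation order. Voxels outside the mask hold the fill
#' value 0 in every map with `converged = FALSE`.
#'
#' @param series A [sir_series()].
#' @param config A [sir_fit_config()].
#' @return An object of class `sir_fit`: 3-D parameter maps (`psr`, `r1f`,
#'   `sf`, `m0f`, optionally `kmf`) and diagnostics (`residual_norm`,
#'   `iterations`, `converged`), plus the scheme, mask and config. Use
#'   [tidy()][generics::tidy] for a per-voxel tibble and
#'   [glance()][generics::glance] for a one-row summary.
#' @export
fit_sir <- function(series, config = sir_fit_config()) {
  stopifnot(inherits(series, "sir_series"))
  if (dim(series$data)[4] != nrow(series$scheme)) {
    stop(sprintf("series has %d volumes but the scheme has %d (ti, td) pairs",
                 dim(series$data)[4], nrow(series$scheme)), call. = FALSE)
  }
  dims <- dim(series$data)
  spatial <- dims[1:3]
  nvox <- prod(spatial)
  mask <- series$mask
  if (is.null(mask)) mask <- array(TRUE, spatial)
  idx <- which(mask)
  sig_mat <- matrix(series$data, nrow = nvox)   # voxels x volumes
  scheme <- series$scheme
  free <- free_param_names(config)

  t0 <- proc.time()[["elapsed"]]
  fit_one <- function(i) {
    unlist(fit_sir_voxel(sig_mat[i, ], scheme, config), use.names = FALSE)
  }
  ncol_out <- length(free) + 3L
  if (config$threads > 1L && .Platform$OS.type == "unix") {
    rows <- parallel::mclapply(idx, fit_one, mc.cores = config$threads,
                               mc.preschedule = TRUE)
    out <- matrix(unlist(rows), ncol = ncol_out, byrow = TRUE)
  } else {
    out <- matrix(0, nrow = length(idx), ncol = ncol_out)
    for (j in seq_along(idx)) out[j, ] <- fit_one(idx[j])
  }
  elapsed <- proc.time()[["elapsed"]] - t0

  maps <- list()
  cols <- c(free, "residual_norm", "iterations", "converged")
  for (k in seq_along(cols)) {
    m <- array(0, spatial)
    m[idx] <- out[, k]
    maps[[cols[k]]] <- m
  }
  maps$converged <- array(as.logical(maps$converged), spatial)
  maps$iterations <- array(as.integer(maps$iterations), spatial)

  structure(list(maps = maps, scheme = scheme, mask = mask, config = config,
                 free = free, n_fitted = length(idx), elapsed = elapsed,
                 reference = series$reference),
            class = "sir_fit")
}

#' @export
print.sir_fit <- function(x, ...) {
  d <- dim(x$maps$psr)
  cat(sprintf("SIR fit: %s grid, %d voxels fitted (%d converged) in %.1f s\n",
              paste(d, collapse = "x"), x$n_fitted,
              sum(x$maps$converged), x$elapsed))
  cat(sprintf("  free parameters: %s\n", paste(x$free, collapse = ", ")))
  if (!x$config$fit_kmf) cat(sprintf("  fixed kmf = %g s^-1\n", x$config$kmf))
  invisible(x)
}
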