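#' 4-D SIR image series container
#'
#' Pairs a 4-D magnitude image array (x, y, z, volume) with the acquisition
#' scheme whose rows index the 4th dimension, and optionally a spatial mask
#' restricting which voxels are fit.
#'
#' @param data 4-D numeric array; the 4th-dimension length must equal the
#'   scheme length.
#' @param scheme A [sir_scheme()] tibble.
#' @param mask Optional 3-D logical (or 0/1) array matching the spatial
#'   dimensions of `data`.
#' @param reference Optional `niftiImage` carrying voxel geometry (affine,
#'   spacing) through to written outputs.
#' @return An object of class `sir_series`.
#' @export
sir_series <- function(data, scheme, mask = NULL, reference = NULL) {
  validate_scheme(scheme)
  if (length(dim(data)) != 4L) {
    stop(sprintf("`data` must be 4-D (x, y, z, volume); got %d dimensions",
                 length(dim(data))), call. = FALSE)
  }
  if (dim(data)[4] != nrow(scheme)) {
    stop(sprintf("series has %d volumes but the scheme has %d (ti, td) pairs",
                 dim(data)[4], nrow(scheme)), call. = FALSE)
  }
  if (!is.null(mask)) {
    if (!identical(dim(mask)[1:3], dim(data)[1:3]) || length(dim(mask)) != 3L) {
      stop(sprintf("mask shape (%s) does not match the series spatial shape (%s)",
                   paste(dim(mask), collapse = "x"),
                   paste(dim(data)[1:3], collapse = "x")), call. = FALSE)
    }
    mask <- array(as.logical(mask), dim(mask))
  }
  structure(list(data = data, scheme = scheme, mask = mask,
                 reference = reference),
            class = "sir_series")
}

#' @export
print.sir_series <- function(x, ...) {
  cat(sprintf("SIR series: %s, %d volumes\n",
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4]))
  cat(sprintf("  scheme (ms): ti = %s; td = %s\n",
              paste(round(x$scheme$ti * 1000), collapse = ", "),
              paste(round(x$scheme$td * 1000), collapse = ", ")))
  if (!is.null(x$mask)) cat(sprintf("  mask: %d voxels\n", sum(x$mask)))
  invisible(x)
}

#' Digital phantom truth grids
#'
#' Ground-truth parameter grids for the simulation study: PSR varies linearly
#' along columns and R1f linearly along rows (both endpoints included), with
#' Sf and M0f spatially constant. The defaults regenerate the validation
#' phantom spanning the white-matter range at 3 T: a 128 x 128 grid with PSR
#' from 5% to 25% and R1f from 0.5 to 1.5 s^-1, Sf = -1, M0f = 1.
#'
#' @param shape Grid dimensions `c(rows, cols)`, each `>= 2`.
#' @param psr_range `c(lo, hi)` PSR range (degenerate `lo == hi` allowed;
#'   inverted ranges are an error).
#' @param r1f_range `c(lo, hi)` R1f range, s^-1.
#' @param sf Constant inversion efficiency (default -1).
#' @param m0f Constant equilibrium magnetization (default 1).
#' @return A tibble of class `sir_phantom` with one row per voxel (columns
#'   `row`, `col`, `psr`, `r1f`, `sf`, `m0f`) and attributes `shape`,
#'   `psr_range`, `r1f_range`. PSR is constant down a column, R1f along a row.
#' @examples
#' ph <- sir_phantom(shape = c(8, 8))
#' range(ph$psr)
#' @export
sir_phantom <- function(shape = c(128, 128), psr_range = c(0.05, 0.25),
                        r1f_range = c(0.5, 1.5), sf = -1, m0f = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 2L)) {
    stop("`shape` must be c(rows, cols) with both >= 2", call. = FALSE)
  }
  for (rg in list(psr = psr_range, r1f = r1f_range)) {
    if (length(rg) != 2L || any(!is.finite(rg)) || rg[1] > rg[2]) {
      stop("parameter ranges must be finite c(lo, hi) with lo <= hi",
           call. = FALSE)
    }
  }
  if (psr_range[1] < 0 || r1f_range[1] <= 0) {
    stop("ranges must be physical: psr >= 0, r1f > 0", call. = FALSE)
  }
  psr_col <- seq(psr_range[1], psr_range[2], length.out = shape[2])
  r1f_row <- seq(r1f_range[1], r1f_range[2], length.out = shape[1])
  grid <- tibble::tibble(
    row = rep(seq_len(shape[1]), times = shape[2]),
    col = rep(seq_len(shape[2]), each = shape[1]),
    psr = rep(psr_col, each = shape[1]),
    r1f = rep(r1f_row, times = shape[2]),
    sf = sf, m0f = m0f)
  structure(grid,
            shape = shape, psr_range = psr_range, r1f_range = r1f_range,
            class = c("sir_phantom", class(tibble::tibble())))
}

#' Truth grid as a matrix
#'
#' @param phantom A [sir_phantom()].
#' @param parameter Which truth grid: `"psr"` or `"r1f"`.
#' @return A rows x cols matrix.
#' @export
phantom_grid <- function(phantom, parameter = c("psr", "r1f")) {
  parameter <- match.arg(parameter)
  shape <- attr(phantom, "shape")
  matrix(phantom[[parameter]], nrow = shape[1], ncol = shape[2])
}

#' Simulate a noise-free SIR series from phantom truth
#'
#' Evaluates the forward model at every phantom voxel for every (tI, tD) pair
#' of the scheme. The output is (rows, cols, 1, n) — one singleton slice axis
#' for NIfTI compatibility. Deterministic: no noise is added here.
#'
#' @param phantom A [sir_phantom()].
#' @param scheme A [sir_scheme()]; defaults to the optimized 4-point scheme.
#' @param kmf Exchange rate used throughout the grid, s^-1.
#' @param sm Macromolecular inversion efficiency.
#' @param r1m Fixed macromolecular relaxation rate, or `NULL` for R1m = R1f.
#' @param magnitude Store `|Mzf|` (default), matching magnitude image data.
#' @return A [sir_series()].
#' @export
simulate_sir_series <- function(phantom, scheme = sir_default_scheme(),
                                kmf = 12.5, sm = 0.83, r1m = NULL,
                                magnitude = TRUE) {
  stopifnot(inherits(phantom, "sir_phantom"))
  validate_scheme(scheme)
  shape <- attr(phantom, "shape")
  n <- nrow(scheme)
  out <- array(0, c(shape[1], shape[2], 1L, n))
  r1m_v <- if (is.null(r1m)) phantom$r1f else r1m
  for (k in seq_len(n)) {
    s <- sir_mz_core(phantom$psr, phantom$r1f, r1m_v, phantom$sf, sm,
                     phantom$m0f, kmf, scheme$ti[k], scheme$td[k])
    if (magnitude) s <- abs(s)
    out[, , 1L, k] <- s   # phantom rows vary fastest, matching array order
  }
  sir_series(out, scheme)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Add Rician noise to a magnitude series
#'
#' Standard two-channel construction: each value `v` becomes
#' `sqrt((v + g1)^2 + g2^2)` with `g1`, `g2` independent zero-mean Gaussians
#' of standard deviation `sigma = m0f / snr`. The output is non-negative
#' everywhere and reproducible from the seed; zero signal yields a Rayleigh
#' distribution. The global RNG state is left untouched.
#'
#' @param series A [sir_series()] or plain numeric array.
#' @param snr Signal-to-noise ratio relative to `m0f` (default 250).
#' @param seed Integer seed (default 20220329).
#' @param m0f Reference magnetization defining the noise scale (default 1).
#' @return Same type as `series`, with noise applied.
#' @export
add_rician_noise <- function(series, snr = 250, seed = 20220329, m0f = 1) {
  if (!is.finite(snr) || snr <= 0) stop("`snr` must be > 0", call. = FALSE)
  x <- if (inherits(series, "sir_series")) series$data else series
  if (!all(is.finite(x))) stop("series contains non-finite values", call. = FALSE)
  sigma <- m0f / snr
  noisy <- with_seed(seed, {
    g1 <- stats::rnorm(length(x), sd = sigma)
    g2 <- stats::rnorm(length(x), sd = sigma)
    array(sqrt((x + g1)^2 + g2^2), dim(x))
  })
  if (inherits(series, "sir_series")) {
    series$data <- noisy
    series
  } else {
    noisy
  }
}
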