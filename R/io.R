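#' Read a 4-D SIR series from NIfTI-1 or MAT
#'
#' Loads the image series, pairs it with the acquisition scheme, and attaches
#' an optional mask. The input must be genuinely 4-D with one volume per
#' (tI, tD) pair; 3-D inputs are rejected rather than reinterpreted. NIfTI
#' voxel geometry (affine, spacing) is carried through to outputs written
#' from the resulting fit.
#'
#' @param path `.nii`, `.nii.gz` or `.mat` file.
#' @param ti,td Inversion and pre-delay time arrays (lengths must equal the
#'   4th dimension of the image).
#' @param units Unit of `ti`/`td`: `"ms"` (default) or `"s"`.
#' @param mask_path Optional NIfTI mask volume (nonzero = fit this voxel).
#' @param mat_var MAT variable name override; default picks the first 4-D
#'   array in the file.
#' @return A [sir_series()].
#' @export
read_sir_series <- function(path, ti, td, units = c("ms", "s"),
                            mask_path = NULL, mat_var = NULL) {
  units <- match.arg(units)
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path),
                               call. = FALSE)
  scheme <- sir_scheme(ti, td, units = units)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  reference <- NULL
  if (ext == "mat") {
    data <- read_mat_array(path, var = mat_var)
  } else {
    img <- RNifti::readNifti(path)
    data <- unclass(img)
    attributes(data) <- list(dim = dim(img))
    reference <- img
  }
  if (length(dim(data)) == 3L) {
    stop(paste0("input is 3-D; a SIR series must be 4-D with one volume per ",
                "(ti, td) pair (3-D stacks are not reinterpreted)"),
         call. = FALSE)
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    # NIfTI readers may drop trailing singleton dimensions
    if (length(dim(m)) == 2L) dim(m) <- c(dim(m), 1L)
    if (length(dim(m)) != 3L || !identical(dim(m), dim(data)[1:3])) {
      stop(sprintf("mask shape (%s) does not match series spatial shape (%s)",
                   paste(dim(m), collapse = "x"),
                   paste(dim(data)[1:3], collapse = "x")), call. = FALSE)
    }
    mask <- array(as.vector(m) != 0, dim(m))
  }
  sir_series(data, scheme, mask = mask, reference = reference)
}

nifti_from <- function(arr, reference, datatype = "float") {
  if (!is.null(reference)) {
    RNifti::asNifti(arr, reference = reference, datatype = datatype)
  } else {
    RNifti::asNifti(arr, datatype = datatype)
  }
}

#' Write a simulated or loaded series to NIfTI
#'
#' @param series A [sir_series()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @param datatype NIfTI storage type (default `"float"`, i.e. float32).
#' @return `path`, invisibly.
#' @export
write_sir_series <- function(series, path, datatype = "float") {
  stopifnot(inherits(series, "sir_series"))
  RNifti::writeNifti(nifti_from(series$data, series$reference, datatype), path)
  invisible(path)
}

#' Write fitted parameter maps to NIfTI with a provenance sidecar
#'
#' One float32 NIfTI volume per map — `psr`, `r1f`, `sf`, `m0f`, `kmf` (when
#' fitted), `residual_norm` — plus `converged` stored as 0/1 integers, all
#' sharing the reference geometry, and a JSON sidecar recording the scheme
#' (in ms), configuration and package version so a run can be reproduced
#' exactly.
#'
#' @param fit A [fit_sir()] result.
#' @param output_dir Directory to create/write into.
#' @param prefix Filename prefix (default `"sir"`).
#' @return Named character vector of the files written, invisibly.
#' @export
write_sir_maps <- function(fit, output_dir, prefix = "sir") {
  stopifnot(inherits(fit, "sir_fit"))
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory: %s", output_dir),
                  call. = FALSE)
  }
  map_names <- c(fit$free, "residual_norm")
  files <- character(0)
  for (nm in map_names) {
    f <- file.path(output_dir, sprintf("%s_%s.nii.gz", prefix, nm))
    RNifti::writeNifti(nifti_from(fit$maps[[nm]], fit$reference, "float"), f)
    files[nm] <- f
  }
  f <- file.path(output_dir, sprintf("%s_converged.nii.gz", prefix))
  conv <- array(as.integer(fit$maps$converged), dim(fit$maps$converged))
  RNifti::writeNifti(nifti_from(conv, fit$reference, "uint8"), f)
  files["converged"] <- f

  cfg <- fit$config
  sidecar <- list(
    toolkit = "sirqmt",
    version = as.character(utils::packageVersion("sirqmt")),
    scheme_ms = list(ti = fit$scheme$ti * 1000, td = fit$scheme$td * 1000),
    model = if (cfg$fit_kmf) "5-parameter (kmf estimated)"
            else "4-parameter (kmf fixed)",
    kmf = cfg$kmf, sm = cfg$sm,
    r1m = if (is.null(cfg$r1m)) "tied to R1f" else cfg$r1m,
    magnitude = cfg$magnitude,
    bounds = list(lower = cfg$lower, upper = cfg$upper),
    init = cfg$init, max_iter = cfg$max_iter,
    ftol = cfg$ftol, ptol = cfg$ptol,
    n_fitted = fit$n_fitted, n_converged = sum(fit$maps$converged),
    elapsed_s = fit$elapsed)
  f <- file.path(output_dir, sprintf("%s_sidecar.json", prefix))
  jsonlite::write_json(sidecar, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  files["sidecar"] <- f
  invisible(files)
}

#' Write a simulated phantom study to disk
#'
#' Writes the noise-free series, the noisy series, the PSR and R1f truth
#' grids (NIfTI), a MAT v5 container mirroring the accepted input formats,
#' and a JSON sidecar with the scheme, seed and parameter ranges.
#'
#' @param phantom A [sir_phantom()].
#' @param noisefree,noisy [sir_series()] objects from [simulate_sir_series()]
#'   and [add_rician_noise()].
#' @param output_dir Directory to write into.
#' @param scheme The [sir_scheme()] used.
#' @param snr,seed,kmf,sm Provenance values recorded in the sidecar.
#' @return Named character vector of files written, invisibly.
#' @export
write_sir_simulation <- function(phantom, noisefree, noisy, output_dir,
                                 scheme, snr, seed, kmf, sm) {
  if (!dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  }
  shape <- attr(phantom, "shape")
  as_vol <- function(v) array(v, c(shape, 1L))
  files <- c(
    noisefree = file.path(output_dir, "sim_noisefree.nii.gz"),
    noisy = file.path(output_dir, "sim_noisy.nii.gz"),
    psr_true = file.path(output_dir, "sim_psr_true.nii.gz"),
    r1f_true = file.path(output_dir, "sim_r1f_true.nii.gz"),
    mat = file.path(output_dir, "sim_noisy.mat"),
    sidecar = file.path(output_dir, "sim_sidecar.json"))
  RNifti::writeNifti(RNifti::asNifti(noisefree$data, datatype = "double"),
                     files["noisefree"])
  RNifti::writeNifti(RNifti::asNifti(noisy$data, datatype = "double"),
                     files["noisy"])
  RNifti::writeNifti(RNifti::asNifti(as_vol(phantom_grid(phantom, "psr")),
                                     datatype = "float"), files["psr_true"])
  RNifti::writeNifti(RNifti::asNifti(as_vol(phantom_grid(phantom, "r1f")),
                                     datatype = "float"), files["r1f_true"])
  write_mat(list(sir_noisy = noisy$data,
                 psr_true = phantom_grid(phantom, "psr"),
                 r1f_true = phantom_grid(phantom, "r1f")), files["mat"])
  sidecar <- list(
    toolkit = "sirqmt",
    version = as.character(utils::packageVersion("sirqmt")),
    shape = shape,
    psr_range = attr(phantom, "psr_range"),
    r1f_range = attr(phantom, "r1f_range"),
    sf = phantom$sf[1], m0f = phantom$m0f[1],
    axis_convention = "PSR varies along columns, R1f along rows",
    scheme_ms = list(ti = scheme$ti * 1000, td = scheme$td * 1000),
    snr = snr, seed = seed, kmf = kmf, sm = sm)
  jsonlite::write_json(sidecar, files["sidecar"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(files)
}
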