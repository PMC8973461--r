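# Minimal MAT v5 (Level 5 MAT-file) support for real numeric arrays.
# Little-endian files only; compressed (zlib) and uncompressed elements are
# read; writing is uncompressed miDOUBLE. MAT v7.3 (HDF5) is not supported.

MI_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 4L, `6` = 4L,
              `7` = 4L, `9` = 8L, `12` = 8L, `13` = 8L)

read_mi_data <- function(raw, type, nbytes) {
  n <- nbytes %/% MI_SIZES[[as.character(type)]]
  switch(as.character(type),
    `1` = as.numeric(readBin(raw, "integer", n, size = 1, signed = TRUE,
                             endian = "little")),
    `2` = as.numeric(readBin(raw, "integer", n, size = 1, signed = FALSE,
                             endian = "little")),
    `3` = as.numeric(readBin(raw, "integer", n, size = 2, signed = TRUE,
                             endian = "little")),
    `4` = as.numeric(readBin(raw, "integer", n, size = 2, signed = FALSE,
                             endian = "little")),
    `5` = as.numeric(readBin(raw, "integer", n, size = 4, endian = "little")),
    `6` = {  # uint32: reinterpret negative signed reads
      x <- as.numeric(readBin(raw, "integer", n, size = 4, endian = "little"))
      x + ifelse(x < 0, 2^32, 0)
    },
    `7` = readBin(raw, "numeric", n, size = 4, endian = "little"),
    `9` = readBin(raw, "numeric", n, size = 8, endian = "little"),
    stop(sprintf("unsupported MAT data type %d", type), call. = FALSE))
}

# splits one data element at offset; returns list(type, data(raw), next_offset)
next_element <- function(buf, off) {
  tag <- readBin(buf[off + 1:4], "integer", 1, size = 4, endian = "little")
  small_bytes <- bitwAnd(bitwShiftR(tag, 16L), 0xFFFFL)
  if (small_bytes > 0L) {       # small data element: type/len packed in 4 bytes
    type <- bitwAnd(tag, 0xFFFFL)
    data <- buf[off + 4 + seq_len(small_bytes)]
    return(list(type = type, data = data, next_off = off + 8L))
  }
  type <- tag
  nbytes <- readBin(buf[off + 5:8], "integer", 1, size = 4, endian = "little")
  data <- if (nbytes > 0) buf[off + 8 + seq_len(nbytes)] else raw(0)
  pad <- (8L - nbytes %% 8L) %% 8L
  list(type = type, data = data, next_off = off + 8L + nbytes + pad)
}

parse_matrix_element <- function(payload) {
  e <- next_element(payload, 0L)                      # array flags (miUINT32)
  flags <- readBin(e$data[1:4], "integer", 1, size = 4, endian = "little")
  class_id <- bitwAnd(flags, 0xFFL)
  e2 <- next_element(payload, e$next_off)             # dimensions (miINT32)
  dims <- readBin(e2$data, "integer", length(e2$data) %/% 4L, size = 4,
                  endian = "little")
  e3 <- next_element(payload, e2$next_off)            # name (miINT8)
  name <- rawToChar(e3$data)
  if (!class_id %in% 6:13) {
    return(list(name = name, value = NULL, class_id = class_id))
  }
  e4 <- next_element(payload, e3$next_off)            # real part
  vals <- read_mi_data(e4$data, e4$type, length(e4$data))
  list(name = name, value = array(vals, dims), class_id = class_id)
}

#' Read arrays from a MAT v5 file
#'
#' Parses a little-endian Level 5 MAT-file and returns its real numeric
#' arrays. Compressed elements are inflated with base R's zlib support.
#' Cell arrays, structs, sparse and complex data are skipped. MAT v7.3
#' (HDF5-based) files are not supported.
#'
#' @param path Path to a `.mat` file.
#' @return Named list of numeric arrays.
#' @export
read_mat <- function(path) {
  buf <- readBin(path, "raw", file.size(path))
  if (length(buf) < 128L) stop("not a MAT v5 file (truncated header)", call. = FALSE)
  endian <- rawToChar(buf[127:128])
  if (endian == "MI") {
    stop("big-endian MAT files are not supported", call. = FALSE)
  }
  if (endian != "IM") stop("not a MAT v5 file (bad endian indicator)", call. = FALSE)
  out <- list()
  off <- 128L
  while (off < length(buf)) {
    e <- next_element(buf, off)
    payload <- e$data
    type <- e$type
    if (type == 15L) {                     # miCOMPRESSED: zlib-wrapped element
      payload <- memDecompress(payload, type = "gzip")
      inner <- next_element(payload, 0L)
      type <- inner$type
      payload <- inner$data
    }
    if (type == 14L) {                     # miMATRIX
      m <- parse_matrix_element(payload)
      if (!is.null(m$value)) out[[m$name]] <- m$value
    }
    off <- e$next_off
  }
  out
}

#' Read a 4-D image array from a MAT v5 file
#'
#' @param path Path to a `.mat` file.
#' @param var Variable name to extract; `NULL` picks the first 4-D array.
#' @return A 4-D numeric array.
#' @export
read_mat_array <- function(path, var = NULL) {
  vars <- read_mat(path)
  if (length(vars) == 0L) stop("no numeric arrays found in MAT file", call. = FALSE)
  if (!is.null(var)) {
    if (!var %in% names(vars)) {
      stop(sprintf("variable `%s` not in MAT file; available: %s",
                   var, paste(names(vars), collapse = ", ")), call. = FALSE)
    }
    return(vars[[var]])
  }
  is4d <- vapply(vars, function(v) length(dim(v)) == 4L, logical(1))
  if (!any(is4d)) {
    stop(sprintf("no 4-D array variable in MAT file; candidates were: %s",
                 paste(sprintf("%s (%s)", names(vars),
                               vapply(vars, function(v)
                                 paste(dim(v), collapse = "x"), character(1))),
                       collapse = ", ")), call. = FALSE)
  }
  vars[[which(is4d)[1]]]
}

pad8 <- function(r) c(r, raw((8L - length(r) %% 8L) %% 8L))

mat_element <- function(type, data) {
  c(writeBin(c(type, length(data)), raw(), size = 4, endian = "little"),
    pad8(data))
}

#' Write numeric arrays to a MAT v5 file
#'
#' Writes each array as an uncompressed double-precision matrix element, so
#' the result is readable by MATLAB, Octave and scipy.io.
#'
#' @param arrays Named list of numeric arrays.
#' @param path Output `.mat` path.
#' @return `path`, invisibly.
#' @export
write_mat <- function(arrays, path) {
  stopifnot(is.list(arrays), length(names(arrays)) == length(arrays))
  txt <- sprintf("MATLAB 5.0 MAT-file, written by sirqmt on %s",
                 format(Sys.time(), "%Y-%m-%d"))
  header <- charToRaw(formatC(txt, width = -116))
  header <- c(header[1:116], raw(8),
              writeBin(c(0x00L, 0x01L), raw(), size = 1),   # version 0x0100
              charToRaw("IM"))
  body <- raw(0)
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    d <- dim(a)
    if (is.null(d)) d <- length(a)
    if (length(d) < 2L) d <- c(d, 1L)
    flags <- writeBin(c(6L, 0L), raw(), size = 4, endian = "little")
    sub <- c(mat_element(6L, flags),                            # array flags
             mat_element(5L, writeBin(as.integer(d), raw(), size = 4,
                                      endian = "little")),      # dimensions
             mat_element(1L, charToRaw(nm)),                    # name
             mat_element(9L, writeBin(as.numeric(a), raw(), size = 8,
                                      endian = "little")))      # real data
    body <- c(body, mat_element(14L, sub))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, body), con)
  invisible(path)
}
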