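# Image containers and on-disk interchange.
#
# Images are plain numeric matrices (row = image row, 0-based (row, col)
# conventions in the documentation).  Validation helpers enforce the shared
# contracts: finite values, minimum size, optional [0, 1] range.

#' Validate a 2-D image matrix
#'
#' @param x Numeric (or complex) matrix.
#' @param min_size Minimum number of rows and columns.
#' @param normalized If `TRUE` additionally require values in `[0, 1]`.
#' @param what Name used in error messages.
#' @return `x`, invisibly.
#' @keywords internal
check_image <- function(x, min_size = 8L, normalized = FALSE, what = "image") {
  if (!is.matrix(x)) stop(what, " must be a matrix", call. = FALSE)
  if (nrow(x) < min_size || ncol(x) < min_size) {
    stop(what, " must be at least ", min_size, "x", min_size, call. = FALSE)
  }
  if (!all(is.finite(Mod(x)))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  if (normalized && is.numeric(x) && (min(x) < 0 || max(x) > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' Normalize an image to [0, 1] by its own maximum
#'
#' Each source high-resolution image is divided by its own maximum before
#' degradation, so all network inputs and outputs share the `[0, 1]` range
#' that the PSNR/SSIM `data_range = 1` convention assumes.
#'
#' @param x Numeric matrix with non-negative values.
#' @return Matrix with maximum 1 (an all-zero image is returned unchanged).
#' @export
normalize_max <- function(x) {
  check_image(x)
  m <- max(x)
  if (m > 0) x / m else x
}

# ---------------------------------------------------------------------------
# NPY v1.0 reader/writer (2-D float64 / complex128 only).  NPY is the
# lossless interchange format of the pipeline so that arrays move freely
# between this package and numpy-based tooling.

npy_magic <- as.raw(c(0x93, utf8ToInt("NUMPY"), 0x01, 0x00))

#' Write a matrix to an NPY file
#'
#' Writes a 2-D double or complex matrix as NPY version 1.0
#' (little-endian `<f8` / `<c16`, Fortran order, which matches R's
#' column-major layout byte for byte).
#'
#' @param x Numeric or complex matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path) {
  stopifnot(is.matrix(x))
  descr <- if (is.complex(x)) "<c16" else "<f8"
  header <- sprintf("{'descr': '%s', 'fortran_order': True, 'shape': (%d, %d), }",
                    descr, nrow(x), ncol(x))
  # total header (magic + 2-byte length + dict + '\n') padded to 64 bytes
  need <- 10L + nchar(header) + 1L
  pad <- (64L - need %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(npy_magic, con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  if (is.complex(x)) {
    writeBin(as.vector(x), con, size = 16, endian = "little")
  } else {
    writeBin(as.vector(as.double(x)), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Read a matrix from an NPY file
#'
#' Supports NPY version 1.0/2.0 files holding 2-D `<f8` or `<c16` arrays in
#' either C or Fortran order.
#'
#' @param path File path.
#' @return A numeric or complex matrix.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, npy_magic[1:6])) stop("not an NPY file: ", path)
  ver <- readBin(con, "raw", 2)
  hlen <- if (as.integer(ver[1]) >= 2) {
    readBin(con, "integer", 1, size = 4, endian = "little")
  } else {
    readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  }
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shape), ",")[[1]])
  if (length(dims) != 2L) stop("read_npy supports 2-D arrays only")
  n <- prod(dims)
  x <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8, endian = "little"),
    "<c16" = readBin(con, "complex", n, size = 16, endian = "little"),
    stop("unsupported NPY dtype: ", descr)
  )
  if (fortran) matrix(x, dims[1], dims[2]) else t(matrix(x, dims[2], dims[1]))
}

#' Write an image preview as PNG
#'
#' Quantized preview export; the lossless interchange format is NPY.
#'
#' @param x Numeric matrix; values are clamped to `[0, 1]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  check_image(x)
  png::writePNG(pmin(pmax(x, 0), 1), path, dpi = NULL)
  invisible(path)
}

#' Clamp an image to [0, 1]
#'
#' Raw network output is unconstrained; clamping happens only at export and
#' before metric computation.
#'
#' @param x Numeric matrix.
#' @return Matrix with values clamped to `[0, 1]`.
#' @export
clamp01 <- function(x) pmin(pmax(x, 0), 1)
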