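#' Validate a 2D intensity image
#'
#' Images are plain numeric matrices of nonnegative, finite intensities with
#' the origin at the top-left corner (row index increases downward). They play
#' a double role in the pipeline: the pixel intensities are both the signal
#' being denoised and the potential entering the Hamiltonian.
#'
#' @param x A numeric matrix (or object coercible to one) with at least
#'   2 rows and 2 columns, all entries finite and `>= 0`.
#' @return The validated numeric matrix, invisibly unchanged apart from
#'   coercion to a base matrix of doubles.
#' @examples
#' img <- as_image(matrix(c(1, 2, 3, 4), 2, 2))
#' @export
as_image <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("image must be at least 2x2, got ", nrow(x), "x", ncol(x), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("image intensities must all be finite", call. = FALSE)
  }
  if (any(x < 0)) {
    stop("image intensities must be nonnegative", call. = FALSE)
  }
  dimnames(x) <- NULL
  x
}

#' Flatten an image to a vector and back
#'
#' Pixels are ordered row-major: pixel (r, c) of an `n_rows x n_cols` image
#' maps to index `(r - 1) * n_cols + c` (1-based). This is the ordering under
#' which the Hamiltonian's `+/- 1` couplings are horizontal neighbours and the
#' `+/- n_cols` couplings are vertical neighbours.
#'
#' @param image A numeric matrix.
#' @return `vectorize()`: a numeric vector of length `nrow * ncol`.
#' @seealso [devectorize()]
#' @export
vectorize <- function(image) {
  image <- as.matrix(image)
  as.vector(t(image))
}

#' @rdname vectorize
#' @param v A numeric vector of length `prod(shape)`.
#' @param shape Integer vector `c(n_rows, n_cols)`.
#' @return `devectorize()`: the `n_rows x n_cols` matrix such that
#'   `devectorize(vectorize(x), dim(x))` is `x` exactly.
#' @export
devectorize <- function(v, shape) {
  shape <- as.integer(shape)
  if (length(shape) != 2L) stop("shape must be c(n_rows, n_cols)", call. = FALSE)
  if (length(v) != prod(shape)) {
    stop("vector length ", length(v), " does not match shape ",
         shape[1L], "x", shape[2L], call. = FALSE)
  }
  matrix(v, nrow = shape[1L], ncol = shape[2L], byrow = TRUE)
}

#' Read and write single-channel images
#'
#' Supported formats, chosen by file extension: grayscale PNG and TIFF
#' (8/16-bit; multi-channel files are averaged to one channel and intensities
#' rescaled to the integer range of the stored bit depth), and CSV matrices of
#' raw intensities (comma-separated rows, no header). CSV round-trips at full
#' double precision; PNG/TIFF quantize to the requested bit depth.
#'
#' @param path File path ending in `.png`, `.tif`/`.tiff`, or `.csv`.
#' @return `read_image()`: a numeric intensity matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png  = png_to_matrix(png::readPNG(path)),
    tif  = ,
    tiff = png_to_matrix(tiff::readTIFF(path)),
    csv  = as.matrix(utils::read.csv(path, header = FALSE)),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  as_image(x)
}

# readPNG/readTIFF return [0,1] arrays, possibly with a channel dimension
png_to_matrix <- function(arr) {
  if (length(dim(arr)) == 3L) {
    n_ch <- dim(arr)[3L]
    arr <- apply(arr[, , seq_len(min(n_ch, 3L)), drop = FALSE], c(1L, 2L), mean)
  }
  arr * 65535
}

#' @rdname read_image
#' @param image Numeric matrix of nonnegative intensities.
#' @param bit_depth 8 or 16; bit depth for TIFF output (PNG is written 8-bit;
#'   ignored for CSV).
#' @return `write_image()`: the path, invisibly.
#' @export
write_image <- function(image, path, bit_depth = 16L) {
  image <- as_image(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.table(format(image, digits = 17, trim = TRUE, scientific = TRUE),
                       path, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    return(invisible(path))
  }
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  hi <- max(image)
  scaled <- if (hi > 0) image / hi else image
  switch(ext,
    png  = png::writePNG(scaled, path),
    tif  = ,
    tiff = tiff::writeTIFF(scaled, path, bits.per.sample = as.integer(bit_depth)),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}
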