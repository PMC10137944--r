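#' Read and write label images and intensity channels as 16-bit TIFF
#'
#' Label images hold integer instance ids (0 = background, up to 65535);
#' they round-trip losslessly through 16-bit TIFF. Intensity channels on the
#' `[0, 1]` scale are quantized to 16 bits on write.
#'
#' @param labels integer matrix of instance labels.
#' @param img numeric matrix in `[0, 1]`.
#' @param path file path (`.tif`/`.tiff`).
#' @return readers return the matrix; writers return `path` invisibly.
#' @export
write_label_image <- function(labels, path) {
  stopifnot(is.matrix(labels))
  if (any(labels < 0) || any(labels > 65535))
    stop("write_label_image: labels must be in [0, 65535]")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' @rdname write_label_image
#' @export
write_channel <- function(img, path) {
  stopifnot(is.matrix(img))
  tiff::writeTIFF(clip01(img), path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_channel <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.numeric(m), nrow(m), ncol(m))
}
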