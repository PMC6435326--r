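#' Read and write single-channel grayscale images
#'
#' One file per channel, PNG or TIFF by extension. Intensities are stored
#' scaled to `[0, 1]` by `scale_max` on write and multiplied back on read.
#' TIFF output is 16-bit; PNG output is 8-bit, so PNG round-trips preserve
#' values only up to 8-bit quantization (`scale_max / 255 / 2`).
#'
#' @param path image file (`.png` or `.tif`/`.tiff`).
#' @param mat numeric intensity matrix.
#' @param scale_max intensity corresponding to full scale.
#' @return `read_image_channel`: a numeric matrix; `write_image_channel`:
#'   the path, invisibly.
#' @export
read_image_channel <- function(path, scale_max = 65535) {
  if (!file.exists(path)) stop_invalid(paste("file not found:", path))
  m <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop_invalid("the 'tiff' package is required for TIFF files")
    }
    tiff::readTIFF(path)
  } else {
    stop_invalid("unsupported image extension (use .png or .tif)")
  }
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m * scale_max
}

#' @rdname read_image_channel
#' @export
write_image_channel <- function(mat, path, scale_max = 65535) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat)) || any(mat < 0) || any(mat > scale_max)) {
    stop_invalid("intensities must be finite and within [0, scale_max]")
  }
  scaled <- mat / scale_max
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(scaled, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop_invalid("the 'tiff' package is required for TIFF files")
    }
    tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  } else {
    stop_invalid("unsupported image extension (use .png or .tif)")
  }
  invisible(path)
}
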