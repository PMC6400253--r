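#' Read and write grayscale microscope images
#'
#' PNG and TIFF round-trips for the `microscope_image` container. RGB input
#' is converted to grayscale by channel averaging. Intensities are kept in
#' \[0, 1\].
#'
#' @param image A `microscope_image` (see [capture_image()]).
#' @param path File path ending in .png, .tif or .tiff.
#' @param bits Bit depth for PNG output (8 or 16).
#' @return `write_image` returns the path invisibly; `read_image` returns a
#'   `microscope_image` (pixel size, beam center and omega default to 1, the
#'   image center and 0 unless supplied).
#' @export
write_image <- function(image, path, bits = 16L) {
  px <- image$pixels
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(px, path, dpi = NULL)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, path, bits.per.sample = as.integer(bits))
  } else {
    stop("unsupported image format: ", ext)
  }
  invisible(path)
}

#' @rdname write_image
#' @param pixel_size um per pixel of the stored image.
#' @param beam_center Pixel (row, col) of the beam position.
#' @param omega Goniometer angle at capture, degrees.
#' @export
read_image <- function(path, pixel_size = 1, beam_center = NULL, omega = 0) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(px)) == 3L) px <- rowMeans(px, dims = 2L)
  if (is.null(beam_center)) beam_center <- (dim(px) + 1) / 2
  structure(
    list(pixels = px, pixel_size = pixel_size, beam_center = beam_center,
         omega = omega),
    class = "microscope_image"
  )
}
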