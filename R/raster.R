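#' Raster image with a physical pixel size
#'
#' A `raster_image` is a numeric matrix of non-negative pixel intensities
#' (interpreted as photon counts) together with the physical pixel size in
#' micrometres. All positions in this package are 1-based `(row, col)`
#' coordinates referring to pixel centres; sub-pixel positions are allowed
#' everywhere.
#'
#' @param pixels Numeric matrix of finite, non-negative intensities.
#' @param pixel_size_um Physical size of one pixel in micrometres (> 0).
#' @param source_id Optional identifier carried into event tables.
#'
#' @return An object of class `raster_image`.
#' @export
#' @examples
#' img <- raster_image(matrix(5, 32, 32), pixel_size_um = 3)
#' dim(img$pixels)
raster_image <- function(pixels, pixel_size_um = 3, source_id = "image") {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    abort("`pixels` must be finite and non-negative")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a single positive number")
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         source_id = as.character(source_id)),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf(
    "<raster_image> %d x %d px, %.3g um/px, source '%s'\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$source_id))
  cat(sprintf("  intensity range [%.4g, %.4g], total %.6g\n",
              min(x$pixels), max(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' Read a single-channel grayscale TIFF as a raster image
#'
#' Multi-page TIFFs are read as their first page with a warning; multi-channel
#' pages are averaged to one channel with a warning. Intensities are rescaled
#' back to integer counts assuming the file was written by
#' [write_raster_tiff()] (16-bit, counts / 65535).
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_um Physical pixel size to attach (micrometres).
#' @param max_count Full-scale count corresponding to intensity 1.0 in the
#'   file; 65535 matches a 16-bit acquisition.
#' @return A [raster_image()].
#' @export
read_raster_tiff <- function(path, pixel_size_um = 3, max_count = 65535) {
  if (!file.exists(path)) abort(sprintf("image file not found: %s", path))
  img <- tiff::readTIFF(path, all = TRUE)
  if (is.list(img)) {
    if (length(img) > 1) warn("multi-page TIFF: using the first page")
    img <- img[[1]]
  }
  if (length(dim(img)) == 3) {
    warn("multi-channel TIFF: averaging channels")
    img <- apply(img, c(1, 2), mean)
  }
  raster_image(img * max_count, pixel_size_um = pixel_size_um,
               source_id = basename(path))
}

#' Write a raster image as a 16-bit grayscale TIFF
#'
#' Counts are stored as `round(pixels) / max_count`, so integer counts up to
#' `max_count` round-trip exactly.
#'
#' @param image A [raster_image()].
#' @param path Output path.
#' @param max_count Full-scale count mapped to 1.0 (default 65535, 16-bit).
#' @return `path`, invisibly.
#' @export
write_raster_tiff <- function(image, path, max_count = 65535) {
  stopifnot(inherits(image, "raster_image"))
  px <- round(image$pixels)
  if (max(px) > max_count) {
    warn("intensities exceed `max_count`; clipping")
    px <- pmin(px, max_count)
  }
  tiff::writeTIFF(px / max_count, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}
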