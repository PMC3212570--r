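#' Calibrated grayscale image
#'
#' The universal input of the pipeline: a 2-d grayscale intensity matrix
#' normalized to \[0, 1\] together with the physical pixel size in
#' micrometres per pixel. Rows index the image y axis, columns the x axis.
#'
#' @param intensities numeric matrix of intensities. Values are rescaled to
#'   \[0, 1\] when `normalize = TRUE` (min-max over the image); otherwise they
#'   must already lie in \[0, 1\].
#' @param pixel_size_um physical size of one pixel in micrometres (> 0).
#' @param normalize rescale intensities to \[0, 1\]? Default `TRUE`.
#' @return an object of class `calibrated_image` with fields `intensities`
#'   and `pixel_size_um`.
#' @examples
#' img <- calibrated_image(matrix(runif(64), 8), pixel_size_um = 1.24)
#' dim(img$intensities)
#' @export
calibrated_image <- function(intensities, pixel_size_um, normalize = TRUE) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stopf("`intensities` must be a numeric matrix")
  if (any(!is.finite(intensities)))
    stopf("`intensities` contains non-finite values")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0)
    stopf("`pixel_size_um` must be a single positive number")
  if (normalize) {
    rng <- range(intensities)
    if (rng[2] > rng[1]) {
      intensities <- (intensities - rng[1]) / (rng[2] - rng[1])
    } else {
      intensities <- matrix(0, nrow(intensities), ncol(intensities))
    }
  } else if (min(intensities) < 0 || max(intensities) > 1) {
    stopf("intensities outside [0, 1]; use normalize = TRUE")
  }
  structure(list(intensities = intensities, pixel_size_um = pixel_size_um),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %.4g um/px, range [%.3f, %.3f]\n",
              nrow(x$intensities), ncol(x$intensities), x$pixel_size_um,
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Binary segmentation mask
#'
#' Per-pixel labeling of an image into cellular (0) and background (1)
#' pixels, tagged with the pipeline stage that produced it.
#'
#' @param labels logical or 0/1 matrix; `TRUE`/1 marks background
#'   ("non-occupied") pixels.
#' @param stage provenance tag, one of `"truth"`, `"patch"`,
#'   `"region-filtered"`, `"final"`.
#' @return an object of class `segmentation_mask`: a logical matrix with a
#'   `stage` attribute (`TRUE` = background).
#' @export
segmentation_mask <- function(labels,
                              stage = c("truth", "patch", "region-filtered", "final")) {
  stage <- match.arg(stage)
  if (!is.matrix(labels)) stopf("`labels` must be a matrix")
  m <- matrix(as.logical(labels), nrow(labels), ncol(labels))
  if (any(is.na(m))) stopf("mask labels must be 0/1 or logical")
  structure(m, stage = stage, class = c("segmentation_mask", "matrix", "array"))
}

mask_stage <- function(mask) attr(mask, "stage") %||% "unknown"

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %d x %d px, stage '%s', background fraction %.3f\n",
              nrow(x), ncol(x), mask_stage(x), mean(x)))
  invisible(x)
}

#' Read a grayscale image from PNG or TIFF
#'
#' Multi-channel files are averaged to a single gray channel. Intensities
#' are min-max normalized to \[0, 1\].
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param pixel_size_um pixel size in micrometres per pixel.
#' @return a [calibrated_image].
#' @export
read_calibrated_image <- function(path, pixel_size_um) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported image format '%s'", ext))
  if (length(dim(arr)) == 3) arr <- apply(arr, c(1, 2), mean)
  calibrated_image(arr, pixel_size_um = pixel_size_um, normalize = TRUE)
}

#' Write an image or mask to disk
#'
#' Images are written as 8-bit grayscale PNG or 16-bit grayscale TIFF
#' depending on the file extension; intensities are quantized from \[0, 1\].
#' Masks are written as 8-bit PNG with background = 255, cellular = 0.
#'
#' @param image a [calibrated_image].
#' @param mask a [segmentation_mask].
#' @param path output path (`.png`, `.tif`/`.tiff` for images; `.png` for
#'   masks).
#' @return the path, invisibly.
#' @export
write_calibrated_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  m <- clamp(image$intensities, 0, 1)
  switch(ext,
    png = png::writePNG(m, target = path),            # 8-bit
    tif = ,
    tiff = tiff::writeTIFF(m, where = path, bits.per.sample = 16L),
    stopf("unsupported image format '%s'", ext))
  invisible(path)
}

#' @rdname write_calibrated_image
#' @export
write_mask <- function(mask, path) {
  if (tolower(tools::file_ext(path)) != "png") stopf("masks are written as PNG")
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), target = path)
  invisible(path)
}

#' Read a binary mask from an 8-bit PNG
#'
#' Pixels above half intensity are background, matching [write_mask]'s
#' convention (background = 255).
#'
#' @param path PNG path.
#' @param stage provenance tag for the returned mask.
#' @return a [segmentation_mask].
#' @export
read_mask <- function(path, stage = "truth") {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  segmentation_mask(arr > 0.5, stage = stage)
}
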