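#' Load a grayscale image from PNG or TIFF
#'
#' Multi-channel (RGB/RGBA) images are collapsed to luminance with
#' Rec. 601 weights (0.299 R + 0.587 G + 0.114 B). PNG values are
#' rescaled from the reader's `[0, 1]` convention to the 0-255 intensity
#' scale; TIFF files are read with their native values preserved
#' (`as.is`), so 16-bit data keeps its real range and float TIFFs pass
#' through unchanged.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return numeric matrix of intensities.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    stop(sprintf("unsupported image format '%s': %s", ext, path),
         call. = FALSE))
  if (length(dim(img)) == 3) {
    ch <- dim(img)[3]
    img <- if (ch >= 3) {
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img[, , 1]
    }
  }
  check_image(img)
  img
}

#' Write a grayscale image as PNG (8-bit) or TIFF (float32)
#'
#' @param image numeric matrix; PNG output is min-max scaled to 8 bits,
#'   TIFF output stores the values as 32-bit floats.
#' @param path destination ending in `.png`, `.tif` or `.tiff`.
#' @export
save_image <- function(image, path) {
  check_image(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    rng <- range(image)
    scaled <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
    png::writePNG(scaled, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image / max(abs(image), 1), path, bits.per.sample = 32L)
  } else {
    stop(sprintf("unsupported image format: %s", path), call. = FALSE)
  }
  invisible(path)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask 0/1 matrix.
#' @param path destination `.png` path.
#' @export
save_mask <- function(mask, path) {
  check_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Read a binary mask from PNG
#'
#' @param path `.png` path; any value above half range is foreground.
#' @return 0/1 integer matrix.
#' @export
load_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- (img > 0.5) * 1L
  dim(m) <- dim(img)
  m
}
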