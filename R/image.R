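# Grayscale image container.  Pixels are stored as a numeric matrix in
# [0, 255], rows = y, cols = x; pixel_spacing is mm per pixel (isotropic),
# NA when unknown (measurements then stay in pixel units).

#' Create an ultrasound image object
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]`
#'   (rows = y, columns = x).
#' @param pixel_spacing Millimetres per pixel, or `NA` when unknown.
#' @return An object of class `ultrasound_image`.
#' @export
ultrasound_image <- function(pixels, pixel_spacing = NA_real_) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!is.na(pixel_spacing) && pixel_spacing <= 0)
    stop("pixel_spacing must be positive (mm per pixel)")
  structure(list(pixels = pixels, pixel_spacing = as.numeric(pixel_spacing)),
            class = "ultrasound_image")
}

#' @export
print.ultrasound_image <- function(x, ...) {
  cat(sprintf("ultrasound image: %d x %d px, spacing %s mm/px\n",
              ncol(x$pixels), nrow(x$pixels),
              ifelse(is.na(x$pixel_spacing), "unknown",
                     format(x$pixel_spacing))))
  invisible(x)
}

#' @rdname ultrasound_image
#' @param img An `ultrasound_image`.
#' @export
image_width <- function(img) ncol(img$pixels)

#' @rdname ultrasound_image
#' @export
image_height <- function(img) nrow(img$pixels)

#' Read / write a grayscale PNG as an ultrasound image
#'
#' `read_image()` loads an 8-bit PNG (colour images are converted to
#' luminance); `write_image()` stores the pixel matrix as grayscale PNG.
#' PNG carries no spacing metadata, so spacing is supplied by the caller
#' (the dataset manifest records it for synthetic scenes).
#'
#' @param path PNG file path.
#' @param pixel_spacing mm per pixel to attach on read.
#' @return `read_image()` returns an `ultrasound_image`; `write_image()`
#'   returns `path` invisibly.
#' @export
read_image <- function(path, pixel_spacing = NA_real_) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) {
    # luminance of RGB(A)
    arr <- 0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
  }
  ultrasound_image(round(arr * 255), pixel_spacing = pixel_spacing)
}

#' @rdname read_image
#' @param img An `ultrasound_image`.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "ultrasound_image"))
  px <- pmin(pmax(round(img$pixels), 0), 255) / 255
  png::writePNG(px, target = path)
  invisible(path)
}
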