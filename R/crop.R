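# Crop geometry: the region around a detected cyst is grown by 0.2 x the
# box's own side length on every side (so the cyst outline fits in the
# crop), resampled to a fixed square input for the heatmap net, and the
# affine transform is kept so predictions can be mapped back onto the
# original image.

#' Affine image-to-crop transform
#'
#' Maps original-image coordinates to crop coordinates:
#' `crop = (image - origin) * scale`.  `scale` has one entry per axis
#' (x, y); the two entries are equal for square boxes.
#'
#' @param origin `caliper_point`: image coordinates of the crop's top-left.
#' @param scale Length-1 or length-2 positive numeric, crop pixels per
#'   image pixel (recycled to x/y).
#' @param out_size Side of the square crop, in pixels.
#' @return An object of class `crop_transform`.
#' @export
crop_transform <- function(origin, scale, out_size) {
  origin <- as_point(origin)
  scale <- as.numeric(scale)
  if (length(scale) == 1L) scale <- c(scale, scale)
  stopifnot(length(scale) == 2L, all(is.finite(scale)), all(scale > 0),
            out_size >= 1)
  structure(list(origin = origin, scale = scale,
                 out_size = as.integer(out_size)),
            class = "crop_transform")
}

#' Map a point from image coordinates into crop coordinates
#'
#' @param p A `caliper_point` in image coordinates.
#' @param t A `crop_transform`.
#' @return A `caliper_point` in crop coordinates.
#' @export
map_image_to_crop <- function(p, t) {
  stopifnot(inherits(t, "crop_transform"))
  p <- as_point(p)
  point((p[["x"]] - t$origin[["x"]]) * t$scale[1L],
        (p[["y"]] - t$origin[["y"]]) * t$scale[2L])
}

#' Map a point from crop coordinates back to image coordinates
#'
#' Exact inverse of [map_image_to_crop()].
#'
#' @param p A `caliper_point` in crop coordinates.
#' @param t A `crop_transform`.
#' @return A `caliper_point` in image coordinates.
#' @export
map_crop_to_image <- function(p, t) {
  stopifnot(inherits(t, "crop_transform"))
  p <- as_point(p)
  point(p[["x"]] / t$scale[1L] + t$origin[["x"]],
        p[["y"]] / t$scale[2L] + t$origin[["y"]])
}

#' Map a bounding box through a crop transform
#'
#' Centre is mapped as a point; each side is scaled by its axis's scale.
#'
#' @param b A `bbox` in image coordinates.
#' @param t A `crop_transform`.
#' @return A `bbox` in crop coordinates.
#' @export
map_bbox_to_crop <- function(b, t) {
  stopifnot(inherits(b, "bbox"), inherits(t, "crop_transform"))
  ctr <- map_image_to_crop(point(b[["cx"]], b[["cy"]]), t)
  bbox(ctr[["x"]], ctr[["y"]], b[["w"]] * t$scale[1L], b[["h"]] * t$scale[2L])
}

#' Extract the expanded crop around a detection
#'
#' The source region spans `[cx - 0.7 w, cx + 0.7 w] x [cy - 0.7 h,
#' cy + 0.7 h]` — each side of the box grown by 0.2 of that axis's length —
#' and is resampled bilinearly to `out_size x out_size`.  Pixels falling
#' outside the image are zero-padded, never clipped, so the crop keeps the
#' geometry the heatmap model was trained on.
#'
#' @param b A `bbox` in image coordinates; must overlap the image.
#' @param img An `ultrasound_image`.
#' @param out_size Output side length in pixels (>= 16).
#' @param expansion Per-side expansion fraction (default 0.2).
#' @return A list with elements `crop` (numeric `out_size x out_size`
#'   matrix, values in `[0, 255]`) and `transform` (a `crop_transform`).
#' @export
expand_crop <- function(b, img, out_size = 256L, expansion = 0.2) {
  stopifnot(inherits(b, "bbox"), inherits(img, "ultrasound_image"))
  if (out_size < 16) stop("out_size must be at least 16")
  f <- 1 + 2 * expansion
  rw <- f * b[["w"]]; rh <- f * b[["h"]]
  x0 <- b[["cx"]] - rw / 2; y0 <- b[["cy"]] - rh / 2
  w <- image_width(img); h <- image_height(img)
  if (x0 + rw < 0 || y0 + rh < 0 || x0 > w - 1 || y0 > h - 1)
    stop("bounding box lies fully outside the image")
  t <- crop_transform(point(x0, y0), c(out_size / rw, out_size / rh), out_size)
  # sample positions of each crop pixel in image coordinates
  xs <- x0 + (seq_len(out_size) - 1) / t$scale[1L]
  ys <- y0 + (seq_len(out_size) - 1) / t$scale[2L]
  list(crop = bilinear_sample(img$pixels, xs, ys), transform = t)
}

# Bilinear interpolation of matrix `m` (rows = y, cols = x, pixel centres at
# 0-based integer coordinates) on the grid xs x ys; outside -> 0.
bilinear_sample <- function(m, xs, ys) {
  h <- nrow(m); w <- ncol(m)
  nx <- length(xs); ny <- length(ys)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  # value of pixel (ix, iy) with zero outside, vectorised over the grid
  px <- function(ix, iy) {
    okx <- ix >= 0 & ix <= w - 1
    oky <- iy >= 0 & iy <= h - 1
    out <- matrix(0, ny, nx)
    if (any(okx) && any(oky)) {
      sub <- m[iy[oky] + 1L, ix[okx] + 1L, drop = FALSE]
      out[oky, okx] <- sub
    }
    out
  }
  wx0 <- matrix(1 - fx, ny, nx, byrow = TRUE)
  wx1 <- matrix(fx, ny, nx, byrow = TRUE)
  wy0 <- matrix(1 - fy, ny, nx)
  wy1 <- matrix(fy, ny, nx)
  px(x0, y0) * wx0 * wy0 + px(x0 + 1, y0) * wx1 * wy0 +
    px(x0, y0 + 1) * wx0 * wy1 + px(x0 + 1, y0 + 1) * wx1 * wy1
}
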