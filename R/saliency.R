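# Saliency-map codec.  A landmark is encoded as an inverted Gaussian well:
# value 0 at the landmark pixel, rising with distance d as
#   v(d) = ceil(max_value * (1 - exp(-d^2 / 2 sigma^2))
#                         / (1 - exp(-radius^2 / 2 sigma^2)))
# capped at max_value - 1 for d < radius, and exactly max_value for
# d >= radius.  The ceiling (rather than rounding) guarantees that the
# landmark pixel is the unique zero and that the saturation plateau is
# exactly the d >= radius set, which makes the arg-min decoder exact.
# The left landmark lives in the G channel of the RGB export, the right
# landmark in the R channel; B is all zero.

#' Saliency encoder parameters
#'
#' @param radius Truncation radius of the Gaussian well, pixels
#'   (default 50): beyond it the map saturates at `max_value`.
#' @param max_value Saturation intensity (default 255).
#' @param sigma Gaussian width in pixels; default `radius / 3`.
#' @return An object of class `encoder_params`.
#' @export
encoder_params <- function(radius = 50, max_value = 255, sigma = radius / 3) {
  stopifnot(radius > 0, max_value > 0, sigma > 0)
  structure(list(radius = as.numeric(radius),
                 max_value = as.numeric(max_value),
                 sigma = as.numeric(sigma)),
            class = "encoder_params")
}

#' Two-channel saliency map
#'
#' @param left_channel,right_channel Numeric matrices of equal size with
#'   values in `[0, 255]`; minimum marks the left / right landmark.
#' @return An object of class `saliency_map`.
#' @export
saliency_map <- function(left_channel, right_channel) {
  stopifnot(is.matrix(left_channel), is.matrix(right_channel),
            all(dim(left_channel) == dim(right_channel)))
  if (min(left_channel) < 0 || max(left_channel) > 255 ||
      min(right_channel) < 0 || max(right_channel) > 255)
    stop("saliency values must lie in [0, 255]")
  structure(list(left_channel = left_channel, right_channel = right_channel,
                 height = nrow(left_channel), width = ncol(left_channel)),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("saliency map: %d x %d px, channel minima %g (left) / %g (right)\n",
              x$width, x$height, min(x$left_channel), min(x$right_channel)))
  invisible(x)
}

encode_channel <- function(p, height, width, params) {
  if (p[["x"]] < 0 || p[["x"]] >= width || p[["y"]] < 0 || p[["y"]] >= height)
    stop("landmark lies outside the map")
  xs <- (seq_len(width) - 1) - p[["x"]]
  ys <- (seq_len(height) - 1) - p[["y"]]
  d2 <- outer(ys^2, xs^2, `+`)
  denom <- 1 - exp(-params$radius^2 / (2 * params$sigma^2))
  v <- ceiling(params$max_value * (1 - exp(-d2 / (2 * params$sigma^2))) / denom)
  v <- pmin(v, params$max_value - 1)
  v[d2 >= params$radius^2] <- params$max_value
  v
}

#' Encode a landmark pair as a saliency map
#'
#' @param pair A `landmark_pair` with both points inside
#'   `[0, width) x [0, height)`.
#' @param height,width Map size in pixels.
#' @param params An [encoder_params()] object.
#' @return A `saliency_map`; per channel, the value is 0 at the landmark
#'   pixel, is non-decreasing in distance, and saturates at
#'   `params$max_value` exactly for distances `>= params$radius`.
#' @export
encode_saliency <- function(pair, height, width, params = encoder_params()) {
  stopifnot(inherits(pair, "landmark_pair"), inherits(params, "encoder_params"))
  saliency_map(encode_channel(pair$left, height, width, params),
               encode_channel(pair$right, height, width, params))
}

# Arg-min of one channel with the decoding tie-break: among pixels attaining
# the minimum value, choose the one closest (Euclidean) to the top-left
# corner (0,0); remaining ties resolved in row-major order (y, then x).
# Returns list(point, value).
decode_channel <- function(ch) {
  mv <- min(ch)
  idx <- which(ch == mv)
  ys <- (idx - 1L) %% nrow(ch)        # 0-based row = y
  xs <- (idx - 1L) %/% nrow(ch)       # 0-based col = x
  d2 <- xs^2 + ys^2
  ord <- order(d2, ys, xs)
  k <- ord[1L]
  list(point = point(xs[k], ys[k]), value = mv)
}

#' Decode a saliency map into a landmark pair
#'
#' Per channel, selects the pixel with the smallest saliency value; when
#' several pixels tie, the one closest to the top-left corner wins
#' (Euclidean distance to `(0, 0)`, then row-major order).  The returned
#' pair is normalised to canonical left/right order.
#'
#' @param map A `saliency_map`.
#' @return A `landmark_pair` (integer pixel coordinates; no sub-pixel
#'   refinement).  If both channel minima fall on the same pixel the pair
#'   would be degenerate and an error is raised; use [postprocess()] for
#'   the repair path.
#' @export
decode_saliency <- function(map) {
  m <- decode_minima(map)
  landmark_pair(m$left$point, m$right$point)
}

# Both channel minima with their values, without pair normalisation.
decode_minima <- function(map) {
  stopifnot(inherits(map, "saliency_map"))
  list(left = decode_channel(map$left_channel),
       right = decode_channel(map$right_channel))
}

#' Export / import a saliency map as 3-channel PNG
#'
#' Channel assignment of the on-disk RGB image: R = right landmark,
#' G = left landmark, B = 0.  Round-trip is bit-exact for integer-valued
#' maps.
#'
#' @param map A `saliency_map` (integer-valued in `[0, 255]`).
#' @param path PNG path.
#' @return `write_saliency_png()` returns `path` invisibly;
#'   `read_saliency_png()` returns a `saliency_map`.
#' @export
write_saliency_png <- function(map, path) {
  stopifnot(inherits(map, "saliency_map"))
  arr <- array(0, dim = c(map$height, map$width, 3L))
  arr[, , 1L] <- map$right_channel / 255
  arr[, , 2L] <- map$left_channel / 255
  png::writePNG(arr, target = path)
  invisible(path)
}

#' @rdname write_saliency_png
#' @export
read_saliency_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) != 3L || dim(arr)[3L] < 3L)
    stop("expected a 3-channel PNG saliency map")
  saliency_map(round(arr[, , 2L] * 255), round(arr[, , 1L] * 255))
}
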