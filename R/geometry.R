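# Coordinate conventions used throughout the package: continuous, 0-based,
# origin at the image top-left, x rightward, y downward.  Pixel (0,0) has its
# centre at coordinate (0,0).  Boxes are stored centre-format (cx, cy, w, h)
# and converted to corner-format only inside overlap math.

#' Create a 2-D point
#'
#' Points are continuous (sub-pixel), 0-based, x rightward / y downward.
#'
#' @param x,y Finite numeric scalars, in pixels.
#' @return An object of class `caliper_point`: a named numeric vector
#'   with elements `x` and `y`.
#' @export
#' @examples
#' point(3.5, 7)
point <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == 1L, length(y) == 1L,
            is.finite(x), is.finite(y))
  structure(c(x = as.numeric(x), y = as.numeric(y)), class = "caliper_point")
}

#' @export
print.caliper_point <- function(x, ...) {
  cat(sprintf("point(%.6g, %.6g)\n", x[["x"]], x[["y"]]))
  invisible(x)
}

#' Distance and midpoint of two points
#'
#' @param a,b `caliper_point` objects.
#' @return `point_distance()`: the Euclidean distance in pixels;
#'   `point_midpoint()`: the midpoint as a `caliper_point`.
#' @export
point_distance <- function(a, b) {
  sqrt((a[["x"]] - b[["x"]])^2 + (a[["y"]] - b[["y"]])^2)
}

#' @rdname point_distance
#' @export
point_midpoint <- function(a, b) {
  point((a[["x"]] + b[["x"]]) / 2, (a[["y"]] + b[["y"]]) / 2)
}

#' Create a caliper landmark pair
#'
#' A pair of salient landmarks marks the two ends of a cyst's longest
#' diameter; it is the unit of measurement of the whole pipeline.  The pair
#' is stored in canonical order: `left$x <= right$x`, ties broken by
#' `left$y <= right$y`.  Inputs in the other order are swapped silently.
#'
#' @param left,right `caliper_point` objects (or length-2 numerics `c(x, y)`).
#' @return An object of class `landmark_pair`: a list with elements
#'   `left` and `right`.
#' @export
#' @examples
#' landmark_pair(point(10, 0), point(0, 0))  # normalised: left = (0,0)
landmark_pair <- function(left, right) {
  left <- as_point(left); right <- as_point(right)
  if (left[["x"]] == right[["x"]] && left[["y"]] == right[["y"]])
    stop("degenerate landmark pair: the two points coincide")
  if (left[["x"]] > right[["x"]] ||
      (left[["x"]] == right[["x"]] && left[["y"]] > right[["y"]])) {
    tmp <- left; left <- right; right <- tmp
  }
  structure(list(left = left, right = right), class = "landmark_pair")
}

as_point <- function(p) {
  if (inherits(p, "caliper_point")) return(p)
  stopifnot(is.numeric(p), length(p) == 2L)
  point(p[[1L]], p[[2L]])
}

#' @export
print.landmark_pair <- function(x, ...) {
  cat(sprintf("landmark pair: (%.6g, %.6g) -- (%.6g, %.6g), length %.6g px\n",
              x$left[["x"]], x$left[["y"]], x$right[["x"]], x$right[["y"]],
              pair_length(x)))
  invisible(x)
}

#' Inter-landmark distance of a pair
#'
#' @param pair A `landmark_pair`.
#' @return Euclidean distance between the two points, in pixels.
#' @export
pair_length <- function(pair) {
  stopifnot(inherits(pair, "landmark_pair"))
  point_distance(pair$left, pair$right)
}

#' Create an axis-aligned bounding box
#'
#' Centre-format box: centre `(cx, cy)`, width `w`, height `h`, all in
#' pixels.  The shorter side `min(w, h)` is the cyst size used by the
#' plausibility gate of [needs_correction()].
#'
#' @param cx,cy Box centre.
#' @param w,h Strictly positive side lengths.
#' @return An object of class `bbox` (named numeric vector).
#' @export
bbox <- function(cx, cy, w, h) {
  stopifnot(is.numeric(c(cx, cy, w, h)), all(is.finite(c(cx, cy, w, h))))
  if (w <= 0 || h <= 0) stop("bbox sides must be strictly positive")
  structure(c(cx = as.numeric(cx), cy = as.numeric(cy),
              w = as.numeric(w), h = as.numeric(h)), class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("bbox: centre (%.6g, %.6g), %g x %g px\n",
              x[["cx"]], x[["cy"]], x[["w"]], x[["h"]]))
  invisible(x)
}

# corner-format (x1, y1, x2, y2) used internally for overlap math
bbox_corners <- function(b) {
  c(x1 = b[["cx"]] - b[["w"]] / 2, y1 = b[["cy"]] - b[["h"]] / 2,
    x2 = b[["cx"]] + b[["w"]] / 2, y2 = b[["cy"]] + b[["h"]] / 2)
}

#' Create a circle
#'
#' @param center A `caliper_point` (or `c(x, y)`).
#' @param radius Strictly positive radius in pixels.
#' @return An object of class `caliper_circle`.
#' @export
circle <- function(center, radius) {
  center <- as_point(center)
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius))
  if (radius <= 0) stop("circle radius must be strictly positive")
  structure(list(center = center, radius = as.numeric(radius)),
            class = "caliper_circle")
}

#' Circle whose diameter is the caliper segment
#'
#' The measured cyst is approximated by the circle whose diameter is the
#' straight line connecting the two paired landmarks; this circle drives
#' both dataset construction and the true-positive criterion.
#'
#' @param pair A `landmark_pair`.
#' @return A `caliper_circle` centred at the pair midpoint with radius half
#'   the inter-landmark distance.
#' @export
#' @examples
#' circle_from_landmarks(landmark_pair(point(0, 0), point(10, 0)))
circle_from_landmarks <- function(pair) {
  stopifnot(inherits(pair, "landmark_pair"))
  circle(point_midpoint(pair$left, pair$right), pair_length(pair) / 2)
}

#' Square bounding box circumscribing the caliper circle
#'
#' The training bounding box of a cyst is the axis-aligned square
#' circumscribing [circle_from_landmarks()]: centred on the circle, side
#' equal to the inter-landmark distance.
#'
#' @param pair A `landmark_pair`.
#' @return A square `bbox` (`w == h`).
#' @export
bbox_from_landmarks <- function(pair) {
  circ <- circle_from_landmarks(pair)
  side <- 2 * circ$radius
  bbox(circ$center[["x"]], circ$center[["y"]], side, side)
}

#' Analytic intersection-over-union of two circles
#'
#' Computes the exact lens-area intersection of two disks divided by the
#' area of their union.  This is the matching score of the evaluation
#' protocol: a prediction is a true positive when the circle IoU against a
#' ground-truth cyst exceeds 0.5.
#'
#' @param a,b `caliper_circle` objects.
#' @return IoU in `[0, 1]`; symmetric in its arguments.
#' @export
#' @examples
#' circle_iou(circle(point(0, 0), 1), circle(point(1, 0), 1))  # ~0.243
circle_iou <- function(a, b) {
  stopifnot(inherits(a, "caliper_circle"), inherits(b, "caliper_circle"))
  r1 <- a$radius; r2 <- b$radius
  d <- point_distance(a$center, b$center)
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) {
    # one disk nested in the other
    inter <- pi * min(r1, r2)^2
    return(inter / (pi * max(r1, r2)^2))
  }
  # lens area of two properly intersecting disks
  a1 <- r1^2 * acos(pmin(1, pmax(-1, (d^2 + r1^2 - r2^2) / (2 * d * r1))))
  a2 <- r2^2 * acos(pmin(1, pmax(-1, (d^2 + r2^2 - r1^2) / (2 * d * r2))))
  k <- (-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2)
  inter <- a1 + a2 - sqrt(max(0, k)) / 2
  union <- pi * r1^2 + pi * r2^2 - inter
  min(1, max(0, inter / union))
}

#' Box IoU and generalised-IoU penalty
#'
#' Returns the plain intersection-over-union of two axis-aligned boxes and
#' the GIoU penalty term `(area(AC) - area(union)) / area(AC)`, where `AC`
#' is the smallest axis-aligned box enclosing both.  `1 - iou + giou_penalty`
#' is the per-box bounding-box regression loss of the detector.
#'
#' @param a,b `bbox` objects.
#' @return Named numeric vector `c(iou = ..., giou_penalty = ...)`.
#' @export
box_overlap <- function(a, b) {
  stopifnot(inherits(a, "bbox"), inherits(b, "bbox"))
  ca <- bbox_corners(a); cb <- bbox_corners(b)
  iw <- max(0, min(ca[["x2"]], cb[["x2"]]) - max(ca[["x1"]], cb[["x1"]]))
  ih <- max(0, min(ca[["y2"]], cb[["y2"]]) - max(ca[["y1"]], cb[["y1"]]))
  inter <- iw * ih
  area_a <- a[["w"]] * a[["h"]]; area_b <- b[["w"]] * b[["h"]]
  union <- area_a + area_b - inter
  ac <- (max(ca[["x2"]], cb[["x2"]]) - min(ca[["x1"]], cb[["x1"]])) *
        (max(ca[["y2"]], cb[["y2"]]) - min(ca[["y1"]], cb[["y1"]]))
  c(iou = inter / union, giou_penalty = (ac - union) / ac)
}
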