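# Coordinate correction.  A decoded caliper pair whose length differs from
# the detected cyst size (shorter bounding-box side l) by more than 5% of l
# is considered implausible — typically both channel minima collapsed into
# the same low-saliency region.  The repair keeps the more confident
# channel minimum (the smaller saliency value) as an anchor and places the
# partner point-symmetrically about the bounding-box centre.

#' Result of the plausibility check / repair step
#'
#' @param pair The final `landmark_pair`.
#' @param corrected Logical: was the symmetric repair applied?
#' @param first_kept Which channel supplied the anchor point
#'   (`"left"`, `"right"`, or `NA` when no correction was applied).
#' @return An object of class `correction_result`.
#' @export
correction_result <- function(pair, corrected, first_kept = NA_character_) {
  stopifnot(inherits(pair, "landmark_pair"), is.logical(corrected))
  structure(list(pair = pair, corrected = corrected, first_kept = first_kept),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("caliper pair (%scorrected): ", if (x$corrected) "" else "un"))
  print(x$pair)
  invisible(x)
}

#' Does a decoded caliper pair need the symmetric repair?
#'
#' True when the inter-landmark distance differs from the cyst size
#' `l = min(w, h)` of the bounding box by strictly more than `tolerance`
#' (default 5%) of `l`.  The decision is scale-invariant: scaling pair and
#' box together leaves it unchanged.
#'
#' @param pair A `landmark_pair` (decoded prediction).
#' @param box The detection `bbox`, in the same coordinates as `pair`.
#' @param tolerance Relative tolerance on the length mismatch.
#' @return Logical flag.
#' @export
#' @examples
#' b <- bbox(50, 50, 100, 100)
#' needs_correction(landmark_pair(point(0, 50), point(104, 50)), b)  # FALSE
#' needs_correction(landmark_pair(point(0, 50), point(110, 50)), b)  # TRUE
needs_correction <- function(pair, box, tolerance = 0.05) {
  stopifnot(inherits(pair, "landmark_pair"), inherits(box, "bbox"))
  l <- min(box[["w"]], box[["h"]])
  abs(pair_length(pair) - l) > tolerance * l
}

#' Repair an implausible caliper pair by point reflection
#'
#' The channel minimum with the smaller saliency value (ties go to the
#' left channel) is kept as the first landmark; the second is placed point
#' symmetrically to it with respect to the bounding-box centre, so the
#' corrected pair's midpoint is exactly the box centre.  If the anchor
#' coincides with the box centre the reflection would collapse the pair;
#' the decoded pair is then returned uncorrected with a warning.
#'
#' @param map The predicted `saliency_map` (crop coordinates).
#' @param bbox_in_crop The detection `bbox` mapped into the same crop
#'   coordinates.
#' @return A `correction_result` with `corrected = TRUE` (unless the
#'   degenerate fallback fires).
#' @export
apply_correction <- function(map, bbox_in_crop) {
  stopifnot(inherits(map, "saliency_map"), inherits(bbox_in_crop, "bbox"))
  m <- decode_minima(map)
  side <- if (m$left$value <= m$right$value) "left" else "right"
  anchor <- m[[side]]$point
  cx <- bbox_in_crop[["cx"]]; cy <- bbox_in_crop[["cy"]]
  partner <- point(2 * cx - anchor[["x"]], 2 * cy - anchor[["y"]])
  if (anchor[["x"]] == partner[["x"]] && anchor[["y"]] == partner[["y"]]) {
    warning("anchor lies at the bounding-box centre; reflection is ",
            "degenerate, returning the uncorrected decode")
    return(correction_result(landmark_pair(m$left$point, m$right$point),
                             corrected = FALSE))
  }
  correction_result(landmark_pair(anchor, partner), corrected = TRUE,
                    first_kept = side)
}

#' Decode a saliency map and correct it when implausible
#'
#' Decodes the per-channel minima; if the resulting caliper length passes
#' the plausibility gate of [needs_correction()] the decoded pair is
#' returned unchanged, otherwise [apply_correction()] repairs it.
#'
#' @inheritParams apply_correction
#' @param tolerance Gate tolerance, forwarded to [needs_correction()].
#' @return A `correction_result`.
#' @export
postprocess <- function(map, bbox_in_crop, tolerance = 0.05) {
  stopifnot(inherits(map, "saliency_map"), inherits(bbox_in_crop, "bbox"))
  m <- decode_minima(map)
  degenerate <- m$left$point[["x"]] == m$right$point[["x"]] &&
    m$left$point[["y"]] == m$right$point[["y"]]
  if (!degenerate) {
    pair <- landmark_pair(m$left$point, m$right$point)
    if (!needs_correction(pair, bbox_in_crop, tolerance))
      return(correction_result(pair, corrected = FALSE))
  }
  apply_correction(map, bbox_in_crop)
}
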