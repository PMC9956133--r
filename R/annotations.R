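# Annotation text format: one cyst per line,
#   cx cy w h x1 y1 x2 y2
# all in pixels, space-separated, 6 decimal places, '#' starts a comment.
# (x1, y1) / (x2, y2) are the left / right caliper landmarks; (cx, cy, w, h)
# is the centre-format bounding box.

#' Create a per-cyst annotation
#'
#' @param pair A `landmark_pair`.
#' @param box A `bbox`; defaults to the square circumscribing the caliper
#'   circle of `pair`.
#' @return An object of class `cyst_annotation`.
#' @export
cyst_annotation <- function(pair, box = bbox_from_landmarks(pair)) {
  stopifnot(inherits(pair, "landmark_pair"), inherits(box, "bbox"))
  structure(list(pair = pair, bbox = box), class = "cyst_annotation")
}

#' Read per-image cyst annotations from a text file
#'
#' Each non-comment line holds eight space-separated numbers
#' `cx cy w h x1 y1 x2 y2` (pixels).  Malformed lines raise an error
#' naming the offending line number.
#'
#' @param path Annotation file path.
#' @return A list of `cyst_annotation` objects (possibly empty).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[[i]])
    if (!nzchar(trimws(ln))) next
    fields <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    if (length(fields) != 8L)
      stop(sprintf("parse error at line %d of '%s': expected 8 fields, got %d",
                   i, path, length(fields)))
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop(sprintf("parse error at line %d of '%s': non-numeric field", i, path))
    out[[length(out) + 1L]] <- cyst_annotation(
      landmark_pair(point(vals[5L], vals[6L]), point(vals[7L], vals[8L])),
      bbox(vals[1L], vals[2L], vals[3L], vals[4L]))
  }
  out
}

#' Write per-image cyst annotations to a text file
#'
#' Values are written with 6 decimal places; [read_annotations()] followed
#' by `write_annotations()` round-trips bit-exactly at that precision.
#'
#' @param annotations List of `cyst_annotation` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  lines <- vapply(annotations, function(a) {
    paste(sprintf("%.6f", c(a$bbox[["cx"]], a$bbox[["cy"]],
                            a$bbox[["w"]], a$bbox[["h"]],
                            a$pair$left[["x"]], a$pair$left[["y"]],
                            a$pair$right[["x"]], a$pair$right[["y"]])),
          collapse = " ")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
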