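# Evaluation protocol: each caliper pair (true or predicted) defines the
# circle whose diameter is the caliper segment; predictions are matched
# one-to-one to ground truth greedily by descending circle IoU, a match
# counting as a true positive when its IoU exceeds the threshold (0.5).
# Position error and diameter length error (DLE) are computed for true
# positives only.

#' Match predicted to true caliper pairs by circle IoU
#'
#' Greedy one-to-one matching in descending circle-IoU order; only pairs
#' with IoU strictly above `iou_threshold` are kept.  Unmatched truths
#' are false negatives, unmatched predictions false positives.
#'
#' @param truth,pred Lists of `landmark_pair` objects for one image.
#' @param iou_threshold True-positive threshold in `(0, 1)` (default 0.5).
#' @return A list of class `match_set` with `matches` (list of
#'   `list(truth_idx, pred_idx, iou)`), `unmatched_truth` and
#'   `unmatched_pred` (integer indices).
#' @export
match_pairs <- function(truth, pred, iou_threshold = 0.5) {
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  nt <- length(truth); np <- length(pred)
  iou <- matrix(0, nt, np)
  if (nt > 0L && np > 0L) {
    tc <- lapply(truth, circle_from_landmarks)
    pc <- lapply(pred, circle_from_landmarks)
    for (i in seq_len(nt))
      for (j in seq_len(np)) iou[i, j] <- circle_iou(tc[[i]], pc[[j]])
  }
  matches <- list()
  used_t <- logical(nt); used_p <- logical(np)
  if (nt > 0L && np > 0L) {
    ord <- order(-iou, row(iou), col(iou))   # descending IoU, stable ties
    for (k in ord) {
      if (iou[k] <= iou_threshold) break
      i <- row(iou)[k]; j <- col(iou)[k]
      if (used_t[i] || used_p[j]) next
      used_t[i] <- TRUE; used_p[j] <- TRUE
      matches[[length(matches) + 1L]] <-
        list(truth_idx = i, pred_idx = j, iou = iou[k])
    }
  }
  structure(list(matches = matches,
                 unmatched_truth = which(!used_t),
                 unmatched_pred = which(!used_p)),
            class = "match_set")
}

#' Caliper position error
#'
#' Sum of the Euclidean distances between corresponding true and
#' predicted landmark points, times the pixel spacing.  The
#' correspondence (identity or swapped) is chosen to minimise the sum,
#' since left/right labels of independent annotators need not agree.
#'
#' @param truth,pred Matched `landmark_pair` objects.
#' @param spacing mm per pixel (default 1: result in pixels).
#' @return Non-negative scalar (mm, or px for `spacing = 1`).
#' @export
position_error <- function(truth, pred, spacing = 1) {
  stopifnot(inherits(truth, "landmark_pair"), inherits(pred, "landmark_pair"))
  direct <- point_distance(truth$left, pred$left) +
    point_distance(truth$right, pred$right)
  swapped <- point_distance(truth$left, pred$right) +
    point_distance(truth$right, pred$left)
  min(direct, swapped) * spacing
}

#' Diameter length error (DLE)
#'
#' Absolute difference between the true and predicted inter-landmark
#' distances, times the pixel spacing.
#'
#' @inheritParams position_error
#' @return Non-negative scalar (mm, or px for `spacing = 1`).
#' @export
dle <- function(truth, pred, spacing = 1) {
  stopifnot(inherits(truth, "landmark_pair"), inherits(pred, "landmark_pair"))
  abs(pair_length(truth) - pair_length(pred)) * spacing
}

#' Evaluate predictions against ground truth across images
#'
#' Aggregates [match_pairs()] over a set of images and derives detection
#' precision/recall plus per-true-positive position errors and DLEs.
#'
#' @param truth,pred Named lists (image id -> list of `landmark_pair`);
#'   the two sets of names must coincide.
#' @param spacing mm per pixel (default 1).
#' @param iou_threshold True-positive circle-IoU threshold.
#' @return An object of class `eval_report`: counts `tp`, `fp`, `fn`,
#'   ratios `precision` and `recall`, numeric vectors `position_errors`
#'   and `dles` (length `tp`), their means/medians, and a per-match data
#'   frame `matches`.
#' @export
evaluate <- function(truth, pred, spacing = 1, iou_threshold = 0.5) {
  if (!setequal(names(truth), names(pred)) ||
      is.null(names(truth)) || is.null(names(pred)))
    stop("truth and prediction image ids do not match")
  tp <- 0L; fp <- 0L; fn <- 0L
  pe <- numeric(0); dl <- numeric(0)
  rows <- list()
  for (id in names(truth)) {
    ms <- match_pairs(truth[[id]], pred[[id]], iou_threshold)
    tp <- tp + length(ms$matches)
    fp <- fp + length(ms$unmatched_pred)
    fn <- fn + length(ms$unmatched_truth)
    for (m in ms$matches) {
      t_pair <- truth[[id]][[m$truth_idx]]
      p_pair <- pred[[id]][[m$pred_idx]]
      e <- position_error(t_pair, p_pair, spacing)
      d <- dle(t_pair, p_pair, spacing)
      pe <- c(pe, e); dl <- c(dl, d)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id, truth_idx = m$truth_idx, pred_idx = m$pred_idx,
        circle_iou = m$iou, position_error = e, dle = d,
        stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image_id = character(0), truth_idx = integer(0),
               pred_idx = integer(0), circle_iou = numeric(0),
               position_error = numeric(0), dle = numeric(0))
  structure(list(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    position_errors = pe, dles = dl,
    mean_position_error = if (tp > 0) mean(pe) else NA_real_,
    median_position_error = if (tp > 0) median(pe) else NA_real_,
    mean_dle = if (tp > 0) mean(dl) else NA_real_,
    median_dle = if (tp > 0) median(dl) else NA_real_,
    spacing = spacing, matches = matches), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  unit <- if (isTRUE(all.equal(x$spacing, 1))) "px" else "mm"
  cat(sprintf("caliper evaluation: TP %d, FP %d, FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  precision %.3f, recall %.3f\n", x$precision, x$recall))
  if (x$tp > 0) {
    cat(sprintf("  position error: mean %.3f, median %.3f %s\n",
                x$mean_position_error, x$median_position_error, unit))
    cat(sprintf("  DLE: mean %.3f, median %.3f %s\n",
                x$mean_dle, x$median_dle, unit))
  }
  invisible(x)
}

#' Export an evaluation report
#'
#' Writes the per-match table as CSV and the summary (counts, ratios,
#' means/medians) as JSON.
#'
#' @param report An `eval_report`.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return `report`, invisibly.
#' @export
export_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  if (!is.null(csv_path))
    write.csv(report$matches, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    summary <- report[c("tp", "fp", "fn", "precision", "recall",
                        "mean_position_error", "median_position_error",
                        "mean_dle", "median_dle", "spacing")]
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
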