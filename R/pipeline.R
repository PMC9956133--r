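# End-to-end orchestration: detect cysts, crop around each detection,
# predict the saliency map, decode + correct, and map the caliper points
# back onto the original image.  Crops are processed one by one, in
# detection-score order; every detection yields exactly one landmark
# pair, so the number of output landmarks is twice the number of
# detections.

#' Run the full caliper-placement pipeline on one image
#'
#' @param image An `ultrasound_image`.
#' @param detector A detector backend (see [detect()]).
#' @param heatmap_model A heatmap backend (see [predict_heatmap()]).
#' @param crop_size Heatmap-model input side; defaults to the model's own
#'   `crop_size` (falls back to 64 for size-agnostic backends such as the
#'   oracle).
#' @param image_id Identifier forwarded to oracle backends.
#' @param correction Apply the plausibility gate + symmetric repair
#'   (default `TRUE`); with `FALSE` the raw decodes are returned.
#' @param square_boxes Replace each detected box by the square of side
#'   `sqrt(w * h)` before cropping (default `TRUE`).  Ground-truth boxes
#'   are squares by construction (they circumscribe the caliper circle),
#'   so squaring removes aspect distortion from the heatmap crop without
#'   moving the box centre.
#' @param ... Passed to [detect()] (e.g. `score_threshold`).
#' @return An object of class `pipeline_result`: a list with `results`
#'   (per detection: `detection`, `pair` in image coordinates,
#'   `corrected`) and `provenance` (model checksums and settings).
#' @export
run_pipeline <- function(image, detector, heatmap_model, crop_size = NULL,
                         image_id = "image", correction = TRUE,
                         square_boxes = TRUE, ...) {
  stopifnot(inherits(image, "ultrasound_image"))
  if (is.null(crop_size)) {
    crop_size <- heatmap_model$crop_size
    if (is.null(crop_size) || is.na(crop_size)) crop_size <- 64L
  }
  if (inherits(heatmap_model, "caliper_heatmap_model") &&
      crop_size != heatmap_model$crop_size)
    stop("crop_size does not match the heatmap model's input size")
  dets <- if (inherits(detector, "oracle_detector"))
    detect(detector, image, image_id = image_id, ...)
  else detect(detector, image, ...)
  ord <- order(vapply(dets, `[[`, numeric(1), "score"), decreasing = TRUE)
  results <- list()
  for (d in dets[ord]) {
    if (square_boxes) {
      side <- sqrt(d$bbox[["w"]] * d$bbox[["h"]])
      d$bbox <- bbox(d$bbox[["cx"]], d$bbox[["cy"]], side, side)
    }
    cr <- expand_crop(d$bbox, image, out_size = crop_size)
    context <- list(image_id = image_id, bbox = d$bbox,
                    transform = cr$transform)
    sm <- if (inherits(heatmap_model, "oracle_heatmap_model"))
      predict_heatmap(heatmap_model, cr$crop, context = context)
    else predict_heatmap(heatmap_model, cr$crop)
    box_in_crop <- map_bbox_to_crop(d$bbox, cr$transform)
    res <- if (correction) postprocess(sm, box_in_crop) else
      correction_result(decode_saliency(sm), corrected = FALSE)
    pair <- landmark_pair(map_crop_to_image(res$pair$left, cr$transform),
                          map_crop_to_image(res$pair$right, cr$transform))
    results[[length(results) + 1L]] <-
      list(detection = d, pair = pair, corrected = res$corrected)
  }
  structure(list(results = results,
                 provenance = list(
                   image_id = image_id,
                   detector = model_fingerprint(detector),
                   heatmap_model = model_fingerprint(heatmap_model),
                   crop_size = crop_size, correction = correction,
                   square_boxes = square_boxes)),
            class = "pipeline_result")
}

model_fingerprint <- function(model) {
  if (!is.null(model$weights)) model_checksum(model) else class(model)[1L]
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline result: %d detection(s), %d landmark(s)\n",
              length(x$results), 2L * length(x$results)))
  for (r in x$results) {
    cat(sprintf("  score %.2f%s: ", r$detection$score,
                if (r$corrected) " (corrected)" else ""))
    print(r$pair)
  }
  invisible(x)
}

#' Landmark pairs of a pipeline result
#'
#' @param result A `pipeline_result`.
#' @return List of `landmark_pair` objects, one per detection.
#' @export
result_pairs <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  lapply(result$results, `[[`, "pair")
}

#' Run the pipeline over a dataset and evaluate it
#'
#' Convenience wrapper: runs [run_pipeline()] on every image of a
#' [load_dataset()]-style dataset and scores the predictions against the
#' dataset's own annotations with [evaluate()].
#'
#' @param dataset Dataset list (`images`, `annotations`, `pixel_spacing`).
#' @param detector,heatmap_model Backends.
#' @param spacing mm/px used for the error metrics; default 1 (pixels).
#' @param ... Passed to [run_pipeline()].
#' @return A list with `report` (an `eval_report`) and `predictions`
#'   (per-image list of `landmark_pair`).
#' @export
measure_dataset <- function(dataset, detector, heatmap_model, spacing = 1,
                            ...) {
  ids <- names(dataset$images)
  preds <- list()
  for (id in ids) {
    pr <- run_pipeline(dataset$images[[id]], detector, heatmap_model,
                       image_id = id, ...)
    preds[[id]] <- result_pairs(pr)
  }
  truth <- lapply(dataset$annotations, function(anns)
    lapply(anns, `[[`, "pair"))
  list(report = evaluate(truth, preds, spacing = spacing),
       predictions = preds)
}
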