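# Detection loss family.  The detector divides the image into an S x S
# grid with B box slots per cell; the total loss is the sum of a GIoU
# bounding-box regression term over object slots, a weighted binary
# cross-entropy on confidences, and a binary cross-entropy on the (single)
# class probability over object cells.

PROB_EPS <- 1e-7

clip_prob <- function(p) pmin(1 - PROB_EPS, pmax(PROB_EPS, p))

bce <- function(p, t) {
  p <- clip_prob(p)
  -(t * log(p) + (1 - t) * log(1 - p))
}

#' Grid-structured detector prediction / target
#'
#' Container for one image's grid output: per cell and box slot a
#' centre-format box, a confidence, a class probability and (for targets)
#' an object-occupancy indicator.
#'
#' @param S Cells per grid side.
#' @param B Box slots per cell.
#' @param boxes Numeric array `c(S, S, B, 4)` of `(cx, cy, w, h)`; may
#'   contain `NA` in slots that carry no object (targets).
#' @param conf Numeric array `c(S, S, B)` of confidences in `[0, 1]`.
#' @param class_prob Numeric array `c(S, S, B)` for the single cyst class.
#' @param obj Logical/0-1 array `c(S, S, B)`: 1 where a ground-truth
#'   object occupies the slot.
#' @return An object of class `grid_prediction`.
#' @export
grid_prediction <- function(S, B, boxes, conf, class_prob, obj) {
  boxes <- array(boxes, dim = c(S, S, B, 4L))
  conf <- array(conf, dim = c(S, S, B))
  class_prob <- array(class_prob, dim = c(S, S, B))
  obj <- array(as.numeric(obj), dim = c(S, S, B))
  structure(list(S = as.integer(S), B = as.integer(B), boxes = boxes,
                 conf = conf, class_prob = class_prob, obj = obj),
            class = "grid_prediction")
}

check_grid_shapes <- function(pred, truth) {
  stopifnot(inherits(pred, "grid_prediction"), inherits(truth, "grid_prediction"))
  if (pred$S != truth$S || pred$B != truth$B)
    stop("grid shapes of prediction and truth do not match")
}

# iterate over object slots of `truth`, calling f(i, j, k)
for_object_slots <- function(truth, f) {
  idx <- which(truth$obj == 1, arr.ind = TRUE)
  if (length(idx) == 0L) return(invisible(NULL))
  idx <- matrix(idx, ncol = 3L)
  for (r in seq_len(nrow(idx))) f(idx[r, 1L], idx[r, 2L], idx[r, 3L])
  invisible(NULL)
}

#' GIoU bounding-box regression loss
#'
#' Sum over ground-truth-occupied slots of
#' `1 - IoU + (area(AC) - area(union)) / area(AC)` between the predicted
#' and true boxes, with `AC` the smallest enclosing box (see
#' [box_overlap()]).
#'
#' @param pred,truth `grid_prediction` objects of matching shape; `truth`
#'   supplies the occupancy indicator and true boxes.
#' @return Non-negative scalar; 0 when every object box is predicted
#'   exactly.
#' @export
giou_loss <- function(pred, truth) {
  check_grid_shapes(pred, truth)
  total <- 0
  for_object_slots(truth, function(i, j, k) {
    pb <- pred$boxes[i, j, k, ]; tb <- truth$boxes[i, j, k, ]
    ov <- box_overlap(bbox(pb[1L], pb[2L], pb[3L], pb[4L]),
                      bbox(tb[1L], tb[2L], tb[3L], tb[4L]))
    total <<- total + 1 - ov[["iou"]] + ov[["giou_penalty"]]
  })
  total
}

#' Confidence loss
#'
#' Binary cross-entropy of predicted confidences against occupancy: full
#' weight on object slots, weight `lambda_nobj` on empty slots.
#' Probabilities are clipped to `(1e-7, 1 - 1e-7)`.
#'
#' @inheritParams giou_loss
#' @param lambda_nobj Weight of the no-object term (default 0.5).
#' @return Non-negative scalar.
#' @export
confidence_loss <- function(pred, truth, lambda_nobj = 0.5) {
  check_grid_shapes(pred, truth)
  obj <- truth$obj
  losses <- bce(pred$conf, obj)
  sum(losses[obj == 1]) + lambda_nobj * sum(losses[obj == 0])
}

#' Classification loss
#'
#' Binary cross-entropy of the single-class probability over object cells.
#'
#' @inheritParams giou_loss
#' @return Non-negative scalar.
#' @export
classification_loss <- function(pred, truth) {
  check_grid_shapes(pred, truth)
  obj <- truth$obj
  losses <- bce(pred$class_prob, array(1, dim = dim(obj)))
  sum(losses[obj == 1])
}

#' Total detection loss
#'
#' Sum of [giou_loss()], [confidence_loss()] and [classification_loss()].
#'
#' @inheritParams confidence_loss
#' @return Non-negative scalar.
#' @export
total_detection_loss <- function(pred, truth, lambda_nobj = 0.5) {
  giou_loss(pred, truth) +
    confidence_loss(pred, truth, lambda_nobj) +
    classification_loss(pred, truth)
}

#' Mean squared error between two saliency maps
#'
#' Mean over all pixels of both channels of the squared intensity
#' difference — the training loss of the heatmap predictor.
#'
#' @param pred,truth `saliency_map` objects of identical size.
#' @return Non-negative scalar.
#' @export
heatmap_mse <- function(pred, truth) {
  stopifnot(inherits(pred, "saliency_map"), inherits(truth, "saliency_map"))
  if (pred$height != truth$height || pred$width != truth$width)
    stop("saliency map shapes do not match")
  n <- 2 * pred$height * pred$width
  (sum((pred$left_channel - truth$left_channel)^2) +
     sum((pred$right_channel - truth$right_channel)^2)) / n
}
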