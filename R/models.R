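# Desk-scale stand-in models.  Both networks are small CPU-trainable
# convolutional nets implemented in compiled code:
#  * detector: 4-stage conv/pool backbone ending in an S x S grid
#    (S = input/16), one box slot per cell, trained with the GIoU +
#    confidence + classification loss family;
#  * heatmap predictor: 3-level nested-U with dense skip aggregation,
#    trained with saliency-map MSE.
# Training is deterministic given the seed: weight init and shuffling both
# derive from R's RNG, and the per-epoch loss trace plus the best-loss
# epoch's weights are kept.

he_init <- function(n_out, n_in, gain = 2) {
  matrix(rnorm(n_out * n_in, sd = sqrt(gain / n_in)), n_out, n_in)
}

# Nested-U weight layout: one 3x3 conv per node X[i][j] (i = level, j =
# skip stage), stored stage-major (all j = 0 nodes, then j = 1, ...),
# followed by the 1x1 output head.  The node's input channel count is
#   j = 0: previous level's width (or 1 for the image input),
#   j > 0: j * width[i] (same-level skips) + width[i+1] (upsampled).
init_heatmap_weights <- function(widths = c(8L, 16L, 32L, 64L)) {
  D <- length(widths) - 1L
  w <- list()
  for (j in 0:D) {
    for (i in 0:(D - j)) {
      cin <- if (j == 0L) {
        if (i == 0L) 1L else widths[i]
      } else {
        j * widths[i + 1L] + widths[i + 2L]
      }
      w[[sprintf("w%d%d", i, j)]] <- he_init(widths[i + 1L], cin * 9)
      w[[sprintf("b%d%d", i, j)]] <- numeric(widths[i + 1L])
    }
  }
  # output bias starts at the saturation plateau (scaled intensity 1) so
  # training spends its epochs on the wells, not on the baseline
  w$wout <- he_init(2L, widths[1L], gain = 1)
  w$bout <- rep(1, 2L)
  w
}

init_detector_weights <- function(widths = c(8L, 16L, 32L, 32L, 48L)) {
  c1 <- widths[1L]; c2 <- widths[2L]; c3 <- widths[3L]; c4 <- widths[4L]
  c5 <- widths[5L]
  list(wc1 = he_init(c1, 1 * 9), bc1 = numeric(c1),
       wc2 = he_init(c2, c1 * 9), bc2 = numeric(c2),
       wc3 = he_init(c3, c2 * 9), bc3 = numeric(c3),
       wc4 = he_init(c4, c3 * 9), bc4 = numeric(c4),
       wc5 = he_init(c5, c4 * 9), bc5 = numeric(c5),
       whead = he_init(6L, c5, gain = 1), bhead = numeric(6L))
}

n_params <- function(weights) sum(vapply(weights, length, numeric(1)))

# cheap content fingerprint used in provenance records
model_checksum <- function(model) {
  v <- unlist(model$weights, use.names = FALSE)
  sprintf("%s-%08x", class(model)[1L],
          bitwAnd(as.integer(sum(abs(v)) * 1e3) + length(v), 0x7fffffffL))
}

#' Training configuration for the stand-in models
#'
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed controlling weight initialisation and epoch
#'   shuffling.
#' @param lambda_nobj No-object confidence weight (detector only).
#' @param anchor Box size prior in pixels (detector only): predicted sides
#'   are `anchor * exp(t)`.
#' @param crop_size Heatmap-net input side in pixels (heatmap only).
#' @param radius Saliency encoding radius used for training targets
#'   (heatmap only).  Default scales the reference radius (50 px at a
#'   256 px crop) to `crop_size`.
#' @param jitter Relative box jitter used to augment training crops
#'   (heatmap only), emulating imperfect detector boxes.
#' @param n_aug Crops generated per annotated cyst (heatmap only): the
#'   first uses the exact ground-truth box, the rest are jittered copies.
#' @param hm_widths Channel widths of the nested-U levels (one entry per
#'   level; length sets the depth).
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 16L, learning_rate = 1e-3,
                         seed = 1L, lambda_nobj = 0.5, anchor = 32,
                         crop_size = 64L, radius = 50 * crop_size / 256,
                         jitter = 0.06, n_aug = 1L,
                         hm_widths = c(8L, 16L, 32L, 64L)) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, n_aug >= 1,
            crop_size %% 2^(length(hm_widths) - 1) == 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 lambda_nobj = lambda_nobj, anchor = anchor,
                 crop_size = as.integer(crop_size), radius = radius,
                 jitter = jitter, n_aug = as.integer(n_aug),
                 hm_widths = as.integer(hm_widths)),
            class = "train_config")
}

shuffle_orders <- function(n, epochs) {
  vapply(seq_len(epochs), function(e) sample.int(n) - 1L, integer(n))
}

# step decay: drop to 20% of the base rate for the last 30% of epochs,
# letting Adam settle into the fine structure (well minima, box corners)
lr_schedule <- function(config) {
  lrs <- rep(config$learning_rate, config$epochs)
  decay_from <- floor(0.7 * config$epochs) + 1L
  if (decay_from <= config$epochs)
    lrs[decay_from:config$epochs] <- 0.2 * config$learning_rate
  lrs
}

# detector schedule: thirds at 1x / 0.3x / 0.1x — box regression keeps
# improving under progressively finer steps
det_lr_schedule <- function(config) {
  ep <- config$epochs
  lrs <- rep(config$learning_rate, ep)
  if (ep >= 3) {
    lrs[(ep %/% 3 + 1L):(2L * ep %/% 3)] <- 0.3 * config$learning_rate
    lrs[(2L * ep %/% 3 + 1L):ep] <- 0.1 * config$learning_rate
  }
  lrs
}

#' Train the stand-in cyst detector
#'
#' Fits the grid detector on a synthetic dataset (see
#' [generate_dataset()]): images are divided into an `S x S` grid
#' (`S = side / 16`) and the net is trained with the sum of the GIoU box
#' loss, the weighted confidence cross-entropy and the class
#' cross-entropy.  The weights of the epoch with the best mean training
#' loss are kept.
#'
#' @param dataset A dataset as returned by [load_dataset()]: a list with
#'   `images` (list of `ultrasound_image`) and `annotations` (list of
#'   per-image annotation lists).
#' @param config A [train_config()].
#' @param augment_flips Quadruple the training set with horizontally,
#'   vertically and doubly mirrored copies (boxes mirrored alongside;
#'   default `TRUE`).  Mirroring is exact for this detector: speckle has
#'   no preferred orientation and boxes are axis-aligned.
#' @return An object of class `caliper_detector` with elements `weights`,
#'   `trace` (per-epoch mean loss), `config` and `input_size`.
#' @export
train_detector <- function(dataset, config = train_config(),
                           augment_flips = TRUE) {
  stopifnot(inherits(config, "train_config"))
  n <- length(dataset$images)
  if (n == 0L) stop("empty training dataset")
  side <- image_height(dataset$images[[1L]])
  stopifnot(side %% 16 == 0, image_width(dataset$images[[1L]]) == side)
  x <- array(0, dim = c(side, side, n))
  for (i in seq_len(n)) x[, , i] <- dataset$images[[i]]$pixels / 255
  boxes <- lapply(dataset$annotations, function(anns) {
    if (length(anns) == 0L) return(matrix(numeric(0), 0L, 4L))
    do.call(rbind, lapply(anns, function(a)
      c(a$bbox[["cx"]], a$bbox[["cy"]], a$bbox[["w"]], a$bbox[["h"]])))
  })
  if (augment_flips) {
    flip_x <- function(m) { if (nrow(m)) m[, 1L] <- (side - 1) - m[, 1L]; m }
    flip_y <- function(m) { if (nrow(m)) m[, 2L] <- (side - 1) - m[, 2L]; m }
    x <- array(c(x,
                 x[, side:1, , drop = FALSE],
                 x[side:1, , , drop = FALSE],
                 x[side:1, side:1, , drop = FALSE]),
               dim = c(side, side, 4L * n))
    boxes <- c(boxes, lapply(boxes, flip_x), lapply(boxes, flip_y),
               lapply(boxes, function(m) flip_y(flip_x(m))))
    n <- 4L * n
  }
  old <- .Random.seed_save(config$seed)
  on.exit(.Random.seed_restore(old))
  weights <- init_detector_weights()
  orders <- shuffle_orders(n, config$epochs)
  fit <- det_train_cpp(weights, x, boxes, stride = 16, anchor = config$anchor,
                       lambda = config$lambda_nobj, epochs = config$epochs,
                       batch_size = config$batch_size,
                       lrs = det_lr_schedule(config), orders = orders)
  structure(list(weights = fit$best_weights, trace = fit$trace,
                 config = config, input_size = side,
                 n_params = n_params(fit$best_weights)),
            class = "caliper_detector")
}

.Random.seed_save <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.caliper_detector <- function(x, ...) {
  cat(sprintf("stand-in grid detector: %d params, %d epochs, best loss %.4g\n",
              x$n_params, length(x$trace), min(x$trace)))
  invisible(x)
}

#' Run the cyst detector on an image
#'
#' Generic over detector backends: the trained stand-in net
#' (`caliper_detector`) decodes its grid output, keeps cells above the
#' score threshold and applies IoU non-maximum suppression; the oracle
#' backend ([oracle_detector()]) returns the ground-truth boxes.
#'
#' @param model A detector backend.
#' @param image An `ultrasound_image`.
#' @param ... Backend-specific arguments; the oracle takes `image_id`.
#' @param score_threshold Minimum confidence kept (default 0.25).
#' @param nms_threshold Box-IoU above which the lower-scored duplicate is
#'   suppressed (default 0.45).
#' @return A list of detections, each `list(bbox, score, class_id)`.
#' @export
detect <- function(model, image, ...) UseMethod("detect")

#' @rdname detect
#' @export
detect.caliper_detector <- function(model, image, ...,
                                    score_threshold = 0.25,
                                    nms_threshold = 0.45) {
  stopifnot(inherits(image, "ultrasound_image"))
  if (is.null(model$weights)) stop("untrained detector model")
  side <- model$input_size
  if (image_height(image) != side || image_width(image) != side)
    stop("image size does not match the detector input size")
  x <- array(image$pixels / 255, dim = c(side, side, 1L))
  raw <- det_forward_cpp(model$weights, x)
  decode_detections(raw[, , , 1L], stride = 16, anchor = model$config$anchor,
                    score_threshold = score_threshold,
                    nms_threshold = nms_threshold)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

decode_detections <- function(raw, stride, anchor, score_threshold,
                              nms_threshold) {
  S <- dim(raw)[1L]
  dets <- list()
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      score <- sigmoid(raw[i, j, 5L]) * sigmoid(raw[i, j, 6L])
      if (score <= score_threshold) next
      cx <- (j - 1 + sigmoid(raw[i, j, 1L])) * stride
      cy <- (i - 1 + sigmoid(raw[i, j, 2L])) * stride
      w <- anchor * exp(min(3, max(-3, raw[i, j, 3L])))
      h <- anchor * exp(min(3, max(-3, raw[i, j, 4L])))
      dets[[length(dets) + 1L]] <-
        list(bbox = bbox(cx, cy, w, h), score = score, class_id = 0L)
    }
  }
  nms(dets, nms_threshold)
}

# IoU-based non-maximum suppression, descending score
nms <- function(dets, threshold) {
  if (length(dets) <= 1L) return(dets)
  ord <- order(vapply(dets, `[[`, numeric(1), "score"), decreasing = TRUE)
  keep <- list()
  for (k in ord) {
    dup <- FALSE
    for (kept in keep) {
      if (box_overlap(dets[[k]]$bbox, kept$bbox)[["iou"]] > threshold) {
        dup <- TRUE; break
      }
    }
    if (!dup) keep[[length(keep) + 1L]] <- dets[[k]]
  }
  keep
}

#' Oracle detector backend
#'
#' Pass-through backend returning the annotated ground-truth boxes with
#' score 1; used to exercise the downstream pipeline independently of
#' detector quality.
#'
#' @param annotations Named list: per image id, a list of
#'   `cyst_annotation` objects.
#' @return An object of class `oracle_detector`.
#' @export
oracle_detector <- function(annotations) {
  structure(list(annotations = annotations), class = "oracle_detector")
}

#' @rdname detect
#' @param image_id Image identifier into the oracle's annotation table.
#' @export
detect.oracle_detector <- function(model, image, ..., image_id) {
  anns <- model$annotations[[image_id]]
  lapply(anns, function(a) list(bbox = a$bbox, score = 1.0, class_id = 0L))
}

#' Train the stand-in heatmap predictor
#'
#' Builds training crops from the annotated cysts (ground-truth boxes,
#' optionally jittered to emulate detector noise, expanded by 0.2 per
#' side and resampled to `config$crop_size`), encodes the landmark pairs
#' as two-channel saliency maps, and fits the nested-U net with
#' saliency-map MSE.  The best-loss epoch's weights are kept.
#'
#' @inheritParams train_detector
#' @return An object of class `caliper_heatmap_model` with elements
#'   `weights`, `trace` (per-epoch MSE on the 0-255 intensity scale),
#'   `config` and `crop_size`.
#' @export
train_heatmap <- function(dataset, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (length(dataset$images) == 0L) stop("empty training dataset")
  old <- .Random.seed_save(config$seed)
  on.exit(.Random.seed_restore(old))
  cs <- config$crop_size
  params <- encoder_params(radius = config$radius)
  xs <- list(); ys <- list()
  for (i in seq_along(dataset$images)) {
    img <- dataset$images[[i]]
    for (a in dataset$annotations[[i]]) {
      for (rep in seq_len(config$n_aug)) {
        b <- a$bbox
        # first copy uses the exact ground-truth box; later copies are
        # jittered to emulate imperfect detector boxes
        if (rep > 1L && config$jitter > 0) {
          b <- bbox(b[["cx"]] + runif(1, -config$jitter, config$jitter) * b[["w"]],
                    b[["cy"]] + runif(1, -config$jitter, config$jitter) * b[["h"]],
                    b[["w"]] * exp(runif(1, -config$jitter, config$jitter)),
                    b[["h"]] * exp(runif(1, -config$jitter, config$jitter)))
        } else if (rep == 1L && config$n_aug == 1L && config$jitter > 0) {
          b <- bbox(b[["cx"]] + runif(1, -config$jitter, config$jitter) * b[["w"]],
                    b[["cy"]] + runif(1, -config$jitter, config$jitter) * b[["h"]],
                    b[["w"]] * exp(runif(1, -config$jitter, config$jitter)),
                    b[["h"]] * exp(runif(1, -config$jitter, config$jitter)))
        }
        cr <- expand_crop(b, img, out_size = cs)
        pl <- map_image_to_crop(a$pair$left, cr$transform)
        pr <- map_image_to_crop(a$pair$right, cr$transform)
        inside <- function(p) p[["x"]] >= 0 && p[["x"]] < cs &&
          p[["y"]] >= 0 && p[["y"]] < cs
        if (!inside(pl) || !inside(pr)) next
        crop <- cr$crop
        if (rep > 1L) {
          # augmented copies also get a random mirror orientation
          # (speckle has none; landmarks are mirrored alongside)
          ori <- sample.int(4L, 1L) - 1L
          if (ori %% 2L == 1L) {          # horizontal mirror
            crop <- crop[, cs:1, drop = FALSE]
            pl[["x"]] <- (cs - 1) - pl[["x"]]
            pr[["x"]] <- (cs - 1) - pr[["x"]]
          }
          if (ori %/% 2L == 1L) {         # vertical mirror
            crop <- crop[cs:1, , drop = FALSE]
            pl[["y"]] <- (cs - 1) - pl[["y"]]
            pr[["y"]] <- (cs - 1) - pr[["y"]]
          }
        }
        sm <- encode_saliency(landmark_pair(pl, pr), cs, cs, params)
        xs[[length(xs) + 1L]] <- crop / 255
        ys[[length(ys) + 1L]] <- sm
      }
    }
  }
  n <- length(xs)
  if (n == 0L) stop("no usable training crops in the dataset")
  x <- array(0, dim = c(cs, cs, n))
  y <- array(0, dim = c(cs, cs, 2L, n))
  for (i in seq_len(n)) {
    x[, , i] <- xs[[i]]
    y[, , 1L, i] <- ys[[i]]$left_channel / 255
    y[, , 2L, i] <- ys[[i]]$right_channel / 255
  }
  weights <- init_heatmap_weights(config$hm_widths)
  orders <- shuffle_orders(n, config$epochs)
  fit <- hm_train_cpp(weights, x, y, epochs = config$epochs,
                      batch_size = config$batch_size,
                      lrs = lr_schedule(config), orders = orders)
  structure(list(weights = fit$best_weights, trace = fit$trace * 255^2,
                 config = config, crop_size = cs,
                 n_params = n_params(fit$best_weights)),
            class = "caliper_heatmap_model")
}

#' @export
print.caliper_heatmap_model <- function(x, ...) {
  cat(sprintf("stand-in nested-U heatmap net: %d params, %d epochs, best MSE %.4g\n",
              x$n_params, length(x$trace), min(x$trace)))
  invisible(x)
}

#' Predict the saliency map of a crop
#'
#' Generic over heatmap backends.  The trained net
#' (`caliper_heatmap_model`) maps a square crop to a two-channel saliency
#' map of the same size with values clipped to `[0, 255]`; the oracle
#' backend re-encodes the ground-truth landmarks.
#'
#' @param model A heatmap backend.
#' @param crop Numeric `crop_size x crop_size` matrix in `[0, 255]`.
#' @param ... Backend-specific arguments; the oracle takes `context`.
#' @return A `saliency_map` of the same spatial size as the crop.
#' @export
predict_heatmap <- function(model, crop, ...) UseMethod("predict_heatmap")

#' @rdname predict_heatmap
#' @param tta Average the prediction over the four mirror orientations of
#'   the crop (default `TRUE`).  Mirroring in x swaps the left/right
#'   channels; the averaged map is mapped back to the original frame, so
#'   the output contract is unchanged and the result stays deterministic.
#' @export
predict_heatmap.caliper_heatmap_model <- function(model, crop, ...,
                                                  tta = TRUE) {
  stopifnot(is.matrix(crop))
  cs <- model$crop_size
  if (nrow(crop) != cs || ncol(crop) != cs)
    stop("crop size does not match the model input size")
  orientations <- if (tta) 0:3 else 0L
  x <- array(0, dim = c(cs, cs, length(orientations)))
  for (k in seq_along(orientations)) {
    v <- crop
    if (orientations[k] %% 2L == 1L) v <- v[, cs:1, drop = FALSE]
    if (orientations[k] %/% 2L == 1L) v <- v[cs:1, , drop = FALSE]
    x[, , k] <- v / 255
  }
  raw <- hm_forward_cpp(model$weights, x)
  left <- matrix(0, cs, cs); right <- matrix(0, cs, cs)
  for (k in seq_along(orientations)) {
    l <- raw[, , 1L, k]; r <- raw[, , 2L, k]
    if (orientations[k] %% 2L == 1L) {
      # undo the x mirror; left and right trade places
      tmp <- l[, cs:1, drop = FALSE]
      l <- r[, cs:1, drop = FALSE]
      r <- tmp
    }
    if (orientations[k] %/% 2L == 1L) {
      l <- l[cs:1, , drop = FALSE]
      r <- r[cs:1, , drop = FALSE]
    }
    left <- left + l; right <- right + r
  }
  left <- left * 255 / length(orientations)
  right <- right * 255 / length(orientations)
  saliency_map(pmin(pmax(left, 0), 255), pmin(pmax(right, 0), 255))
}

#' Oracle heatmap backend
#'
#' Re-encodes the annotated landmark pair of the cyst whose box best
#' overlaps the crop's source box; requires a `context` with the crop
#' transform and image id (supplied by [run_pipeline()]).
#'
#' @inheritParams oracle_detector
#' @param params [encoder_params()] used for re-encoding.
#' @return An object of class `oracle_heatmap_model`.
#' @export
oracle_heatmap_model <- function(annotations, params = encoder_params()) {
  structure(list(annotations = annotations, params = params,
                 crop_size = NA_integer_),
            class = "oracle_heatmap_model")
}

#' @rdname predict_heatmap
#' @param context List with `image_id`, `bbox` (the detection, image
#'   coordinates) and `transform` (the crop's `crop_transform`).
#' @export
predict_heatmap.oracle_heatmap_model <- function(model, crop, ..., context) {
  anns <- model$annotations[[context$image_id]]
  if (length(anns) == 0L) stop("oracle heatmap backend has no annotation ",
                               "for image ", context$image_id)
  ious <- vapply(anns, function(a)
    box_overlap(a$bbox, context$bbox)[["iou"]], numeric(1))
  a <- anns[[which.max(ious)]]
  t <- context$transform
  pair <- landmark_pair(map_image_to_crop(a$pair$left, t),
                        map_image_to_crop(a$pair$right, t))
  encode_saliency(pair, nrow(crop), ncol(crop), model$params)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file embedding the weights, the full
#' training configuration (including its seed) and the loss trace.
#'
#' @param model A `caliper_detector` or `caliper_heatmap_model`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, c("caliper_detector", "caliper_heatmap_model")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, c("caliper_detector", "caliper_heatmap_model")))
    stop("not a sonocaliper checkpoint: ", path)
  model
}
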