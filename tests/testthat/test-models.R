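test_that("the heatmap net's analytic gradient matches finite differences", {
  set.seed(151)
  w <- sonocaliper:::init_heatmap_weights(c(3L, 4L, 5L))
  x <- array(runif(16 * 16), dim = c(16, 16, 1))
  y <- array(runif(16 * 16 * 2), dim = c(16, 16, 2, 1))
  r <- sonocaliper:::hm_lossgrad_cpp(w, x, y)
  for (nm in c("w00", "b11", "w02", "wout", "bout")) {
    for (k in sample(length(w[[nm]]), min(3, length(w[[nm]])))) {
      h <- 1e-6
      wp <- w; wp[[nm]][k] <- wp[[nm]][k] + h
      wm <- w; wm[[nm]][k] <- wm[[nm]][k] - h
      fd <- (sonocaliper:::hm_lossgrad_cpp(wp, x, y)$loss -
               sonocaliper:::hm_lossgrad_cpp(wm, x, y)$loss) / (2 * h)
      expect_equal(r$grads[[nm]][k], fd, tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic given the seed", {
  ds <- tiny_dataset()
  cfg <- train_config(epochs = 3, batch_size = 4, seed = 33,
                      crop_size = 32L, hm_widths = c(4L, 8L, 12L))
  h1 <- train_heatmap(ds, cfg)
  h2 <- train_heatmap(ds, cfg)
  expect_identical(h1$trace, h2$trace)
  expect_identical(h1$weights, h2$weights)
  d1 <- train_detector(ds, train_config(epochs = 3, batch_size = 4,
                                        seed = 33))
  d2 <- train_detector(ds, train_config(epochs = 3, batch_size = 4,
                                        seed = 33))
  expect_identical(d1$trace, d2$trace)
  # a different seed gives a different trajectory
  d3 <- train_detector(ds, train_config(epochs = 3, batch_size = 4,
                                        seed = 34))
  expect_false(identical(d1$trace, d3$trace))
})

test_that("both stand-in trainers overfit a 10-image set", {
  ds <- tiny_dataset()
  hm <- train_heatmap(ds, train_config(epochs = 200, batch_size = 8,
                                       learning_rate = 2e-3, seed = 2,
                                       crop_size = 32L,
                                       hm_widths = c(6L, 12L, 24L)))
  expect_lt(utils::tail(hm$trace, 1), 0.05 * hm$trace[1])
  det <- train_detector(ds, train_config(epochs = 200, batch_size = 8,
                                         learning_rate = 2e-3, seed = 2))
  expect_lt(utils::tail(det$trace, 1), 0.05 * det$trace[1])
  # saved weights are the best epoch's: nothing in the trace is lower
  expect_true(all(det$trace >= min(det$trace)))
})

test_that("model contracts reject bad inputs", {
  ds <- tiny_dataset()
  expect_error(train_detector(list(images = list(), annotations = list())),
               "empty")
  expect_error(train_heatmap(list(images = list(), annotations = list())),
               "empty")
  det <- structure(list(weights = NULL), class = "caliper_detector")
  expect_error(detect(det, ds$images[[1]]), "untrained")
})

test_that("predict_heatmap honours the shape contract", {
  ds <- tiny_dataset()
  hm <- train_heatmap(ds, train_config(epochs = 2, batch_size = 8,
                                       crop_size = 32L,
                                       hm_widths = c(4L, 8L, 12L)))
  crop <- matrix(runif(32 * 32, 0, 255), 32, 32)
  sm <- predict_heatmap(hm, crop)
  expect_s3_class(sm, "saliency_map")
  expect_equal(c(sm$height, sm$width), c(32L, 32L))
  expect_true(all(sm$left_channel >= 0 & sm$left_channel <= 255))
  expect_error(predict_heatmap(hm, matrix(0, 64, 64)), "size")
})

test_that("oracle backends pass annotations through exactly", {
  ds <- tiny_dataset()
  id <- names(ds$images)[1]
  odet <- oracle_detector(ds$annotations)
  dets <- detect(odet, ds$images[[id]], image_id = id)
  expect_length(dets, length(ds$annotations[[id]]))
  expect_equal(dets[[1]]$bbox, ds$annotations[[id]][[1]]$bbox)
  expect_equal(dets[[1]]$score, 1.0)

  ohm <- oracle_heatmap_model(ds$annotations,
                              params = encoder_params(radius = 12.5))
  a <- ds$annotations[[id]][[1]]
  cr <- expand_crop(a$bbox, ds$images[[id]], out_size = 64)
  sm <- predict_heatmap(ohm, cr$crop,
                        context = list(image_id = id, bbox = a$bbox,
                                       transform = cr$transform))
  ref <- encode_saliency(
    landmark_pair(map_image_to_crop(a$pair$left, cr$transform),
                  map_image_to_crop(a$pair$right, cr$transform)),
    64, 64, encoder_params(radius = 12.5))
  expect_identical(sm$left_channel, ref$left_channel)
})

test_that("non-maximum suppression removes overlapping duplicates", {
  d <- function(cx, s) list(bbox = bbox(cx, 50, 30, 30), score = s,
                            class_id = 0L)
  kept <- sonocaliper:::nms(list(d(50, 0.6), d(52, 0.9), d(120, 0.5)), 0.45)
  expect_length(kept, 2L)
  expect_equal(kept[[1]]$score, 0.9)     # the stronger duplicate survives
  expect_equal(kept[[2]]$bbox[["cx"]], 120)
})

test_that("checkpoints round-trip models with config and seed", {
  ds <- tiny_dataset()
  hm <- train_heatmap(ds, train_config(epochs = 2, batch_size = 8,
                                       seed = 44, crop_size = 32L,
                                       hm_widths = c(4L, 8L, 12L)))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(hm, path)
  back <- load_checkpoint(path)
  expect_identical(back$weights, hm$weights)
  expect_equal(back$config$seed, 44L)
  saveRDS(list(1, 2), path)
  expect_error(load_checkpoint(path), "checkpoint")
})
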