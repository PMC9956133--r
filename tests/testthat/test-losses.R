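# Toy grid fixtures: S = 2, B = 1, everything explicit.
empty_grid <- function(S = 2, B = 1) {
  grid_prediction(S, B,
                  boxes = array(NA_real_, c(S, S, B, 4)),
                  conf = array(0.5, c(S, S, B)),
                  class_prob = array(0.5, c(S, S, B)),
                  obj = array(0, c(S, S, B)))
}

with_object <- function(g, i, j, box, conf = 1, class_prob = 1) {
  g$boxes[i, j, 1, ] <- box
  g$conf[i, j, 1] <- conf
  g$class_prob[i, j, 1] <- class_prob
  g$obj[i, j, 1] <- 1
  g
}

test_that("GIoU loss matches hand-computed toy grids", {
  truth <- with_object(empty_grid(), 1, 1, c(0.5, 0.5, 1, 1))
  perfect <- with_object(empty_grid(), 1, 1, c(0.5, 0.5, 1, 1))
  expect_equal(giou_loss(perfect, truth), 0)
  # unit squares two cells apart: 1 - 0 + 1/3
  off <- with_object(empty_grid(), 1, 1, c(2.5, 0.5, 1, 1))
  expect_equal(giou_loss(off, truth), 4 / 3)
  # no object slots -> empty sum
  expect_equal(giou_loss(empty_grid(), empty_grid()), 0)
  expect_error(giou_loss(empty_grid(2), empty_grid(3)), "shape")
})

test_that("confidence loss is weighted BCE with clipped probabilities", {
  S <- 2
  truth <- with_object(empty_grid(S), 1, 1, c(0.5, 0.5, 1, 1))
  # perfect confidences after clipping: at most S^2 * B * 2e-7
  perfect <- truth
  perfect$conf <- truth$obj
  expect_lte(confidence_loss(perfect, truth), S^2 * 2 * 1e-7 * 1.01)
  # one object slot at 0.5 and empty slots perfect -> ln 2
  half <- truth; half$conf <- truth$obj; half$conf[1, 1, 1] <- 0.5
  expect_equal(confidence_loss(half, truth), log(2), tolerance = 1e-6)
  # one empty slot at 0.5, lambda 0.5 -> 0.5 ln 2
  t0 <- empty_grid(1)
  p0 <- empty_grid(1); p0$conf[1, 1, 1] <- 0.5
  expect_equal(confidence_loss(p0, t0, lambda_nobj = 0.5), 0.5 * log(2))
})

test_that("classification loss covers object cells only", {
  truth <- with_object(empty_grid(), 2, 1, c(0.5, 0.5, 1, 1))
  p <- truth
  expect_lt(classification_loss(p, truth), 1e-6)
  p$class_prob[2, 1, 1] <- 0.5
  expect_equal(classification_loss(p, truth), log(2), tolerance = 1e-6)
  expect_equal(classification_loss(empty_grid(), empty_grid()), 0)
})

test_that("total detection loss is the sum of its three terms", {
  truth <- with_object(empty_grid(), 1, 1, c(0.5, 0.5, 1, 1))
  pred <- with_object(empty_grid(), 1, 1, c(2.5, 0.5, 1, 1),
                      conf = 0.5, class_prob = 0.5)
  pred$conf[pred$obj == 0] <- 1e-7   # empty slots perfect
  expect_equal(total_detection_loss(pred, truth),
               4 / 3 + 2 * log(2), tolerance = 1e-6)
  # worsening one component strictly increases the total
  worse <- pred; worse$class_prob[1, 1, 1] <- 0.25
  expect_gt(total_detection_loss(worse, truth),
            total_detection_loss(pred, truth))
})

test_that("heatmap MSE equals the elementwise oracle", {
  a <- encode_saliency(landmark_pair(point(10, 10), point(50, 50)), 64, 64)
  expect_equal(heatmap_mse(a, a), 0)
  # constant offset c everywhere -> c^2
  b <- saliency_map(matrix(3, 64, 64), matrix(3, 64, 64))
  z <- saliency_map(matrix(0, 64, 64), matrix(0, 64, 64))
  expect_equal(heatmap_mse(b, z), 9)
  set.seed(71)
  for (k in 1:20) {
    m1 <- saliency_map(matrix(runif(64, 0, 255), 8, 8),
                       matrix(runif(64, 0, 255), 8, 8))
    m2 <- saliency_map(matrix(runif(64, 0, 255), 8, 8),
                       matrix(runif(64, 0, 255), 8, 8))
    oracle <- (sum((m1$left_channel - m2$left_channel)^2) +
                 sum((m1$right_channel - m2$right_channel)^2)) / 128
    expect_equal(heatmap_mse(m1, m2), oracle, tolerance = 1e-9)
  }
  expect_error(heatmap_mse(m1, saliency_map(matrix(0, 4, 4),
                                            matrix(0, 4, 4))), "shape")
})

test_that("the compiled GIoU gradient matches finite differences", {
  fd_grad <- function(pb, tb) {
    f <- function(v) {
      o <- box_overlap(bbox(v[1], v[2], v[3], v[4]),
                       bbox(tb[1], tb[2], tb[3], tb[4]))
      1 - o[["iou"]] + o[["giou_penalty"]]
    }
    h <- 1e-6
    vapply(1:4, function(i) {
      a <- pb; a[i] <- a[i] + h
      b <- pb; b[i] <- b[i] - h
      (f(a) - f(b)) / (2 * h)
    }, numeric(1))
  }
  set.seed(81)
  for (k in 1:20) {
    pb <- c(runif(2, 20, 60), runif(2, 10, 40))
    tb <- c(runif(2, 20, 60), runif(2, 10, 40))
    r <- sonocaliper:::giou_grad_cpp(pb, tb)
    o <- box_overlap(bbox(pb[1], pb[2], pb[3], pb[4]),
                     bbox(tb[1], tb[2], tb[3], tb[4]))
    expect_equal(r$loss, 1 - o[["iou"]] + o[["giou_penalty"]],
                 tolerance = 1e-9)
    expect_equal(r$grad, fd_grad(pb, tb), tolerance = 1e-4)
  }
})

test_that("the compiled detection loss agrees with the reference formulas", {
  set.seed(91)
  S <- 8L; stride <- 16; anchor <- 32; lambda <- 0.5
  raw <- array(rnorm(S * S * 6, sd = 0.5), dim = c(S, S, 6, 1))
  boxes <- matrix(c(40, 56, 30, 28,  100, 90, 44, 40), 2, 4, byrow = TRUE)
  cpp <- sonocaliper:::det_batch_loss_cpp(raw, list(boxes), stride, anchor,
                                          lambda)
  # rebuild the same prediction/truth grids in R
  sig <- function(z) 1 / (1 + exp(-z))
  pred <- empty_grid(S); truth <- empty_grid(S)
  pred$conf <- array(sig(raw[, , 5, 1]), c(S, S, 1))
  pred$class_prob <- array(sig(raw[, , 6, 1]), c(S, S, 1))
  for (i in 1:S) for (j in 1:S) {
    pred$boxes[i, j, 1, ] <- c(
      (j - 1 + sig(raw[i, j, 1, 1])) * stride,
      (i - 1 + sig(raw[i, j, 2, 1])) * stride,
      anchor * exp(min(3, max(-3, raw[i, j, 3, 1]))),
      anchor * exp(min(3, max(-3, raw[i, j, 4, 1]))))
  }
  for (r in 1:nrow(boxes)) {
    j <- floor(boxes[r, 1] / stride) + 1
    i <- floor(boxes[r, 2] / stride) + 1
    truth <- with_object(truth, i, j, boxes[r, ])
  }
  ref <- total_detection_loss(pred, truth, lambda_nobj = lambda)
  expect_equal(cpp[1], ref, tolerance = 1e-8)
})
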