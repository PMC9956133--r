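# Helper: a saliency map whose channel minima sit at given points with
# given values, everything else at 255.
map_with_minima <- function(left_pt, left_val, right_pt, right_val,
                            side = 100) {
  lc <- matrix(255, side, side); rc <- matrix(255, side, side)
  lc[left_pt[2] + 1, left_pt[1] + 1] <- left_val
  rc[right_pt[2] + 1, right_pt[1] + 1] <- right_val
  saliency_map(lc, rc)
}

test_that("the 5% plausibility gate follows the strict inequality", {
  b <- bbox(50, 50, 100, 100)
  pair_of_len <- function(l) landmark_pair(point(0, 50), point(l, 50))
  expect_false(needs_correction(pair_of_len(104), b))
  expect_false(needs_correction(pair_of_len(105), b))  # exactly 5%: no
  expect_true(needs_correction(pair_of_len(110), b))
  expect_true(needs_correction(pair_of_len(94), b))    # short pairs too
  # l is the shorter side for non-square boxes
  expect_false(needs_correction(pair_of_len(52), bbox(50, 50, 100, 50)))
  expect_true(needs_correction(pair_of_len(100), bbox(50, 50, 100, 50)))
})

test_that("the gate decision is scale-invariant", {
  set.seed(61)
  for (k in 1:25) {
    pair <- random_pair()
    b <- bbox(runif(1, 20, 80), runif(1, 20, 80),
              runif(1, 10, 60), runif(1, 10, 60))
    base <- needs_correction(pair, b)
    for (s in c(0.1, 3, 250)) {
      sp <- landmark_pair(point(pair$left[["x"]] * s, pair$left[["y"]] * s),
                          point(pair$right[["x"]] * s, pair$right[["y"]] * s))
      sb <- bbox(b[["cx"]] * s, b[["cy"]] * s, b[["w"]] * s, b[["h"]] * s)
      expect_identical(needs_correction(sp, sb), base)
    }
  }
})

test_that("the repair reflects the stronger minimum about the box centre", {
  m <- map_with_minima(c(30, 40), 3, c(32, 41), 7)
  res <- apply_correction(m, bbox(50, 50, 40, 40))
  expect_true(res$corrected)
  expect_identical(res$first_kept, "left")    # smaller value wins
  # anchor (30,40), centre (50,50) -> partner (70,60)
  expect_equal(unname(res$pair$left), c(30, 40))
  expect_equal(unname(res$pair$right), c(70, 60))
  # midpoint is exactly the box centre
  mid <- sonocaliper:::point_midpoint(res$pair$left, res$pair$right)
  expect_equal(unname(mid), c(50, 50), tolerance = 1e-12)
  # reflection geometry: |p1 - p2| = 2 |anchor - centre|
  expect_equal(pair_length(res$pair),
               2 * sonocaliper:::point_distance(point(30, 40), point(50, 50)))

  # right channel supplies the anchor when its minimum is smaller
  m2 <- map_with_minima(c(30, 40), 9, c(32, 41), 2)
  expect_identical(apply_correction(m2, bbox(50, 50, 40, 40))$first_kept,
                   "right")
})

test_that("an anchor at the box centre degenerates with a warning", {
  m <- map_with_minima(c(50, 50), 1, c(60, 60), 5)
  expect_warning(res <- apply_correction(m, bbox(50, 50, 40, 40)),
                 "degenerate")
  expect_false(res$corrected)
})

test_that("postprocess leaves plausible decodes untouched", {
  # minima 40 px apart, box shorter side 40: within 5%
  m <- map_with_minima(c(20, 50), 4, c(60, 50), 6)
  res <- postprocess(m, bbox(40, 50, 40, 40))
  expect_false(res$corrected)
  expect_equal(unname(res$pair$left), c(20, 50))
  expect_equal(unname(res$pair$right), c(60, 50))
})

test_that("collapsed decodes are repaired to a centred caliper pair", {
  # both minima in the same low-saliency spot, far shorter than the box
  m <- map_with_minima(c(42, 48), 2, c(44, 49), 3)
  res <- postprocess(m, bbox(50, 50, 60, 60))
  expect_true(res$corrected)
  mid <- sonocaliper:::point_midpoint(res$pair$left, res$pair$right)
  expect_equal(unname(mid), c(50, 50), tolerance = 1e-9)
})

test_that("postprocess is idempotent once the gate passes", {
  # anchor (42,48) is 8.246 px from the centre, so the repaired caliper is
  # 16.49 px long: within 5% of a 16 px box side, so the gate closes
  m <- map_with_minima(c(42, 48), 2, c(44, 49), 3)
  box <- bbox(50, 50, 16, 16)
  res <- postprocess(m, box)
  expect_true(res$corrected)
  expect_false(needs_correction(res$pair, box))
  # re-encode the corrected pair and run again: nothing changes
  sm2 <- encode_saliency(res$pair, 100, 100, encoder_params(radius = 8))
  res2 <- postprocess(sm2, box)
  expect_false(res2$corrected)
  expect_equal(unname(res2$pair$left), unname(res$pair$left))
  expect_equal(unname(res2$pair$right), unname(res$pair$right))
})

test_that("both channel minima on one pixel still yields a repaired pair", {
  lc <- matrix(255, 100, 100); rc <- matrix(255, 100, 100)
  lc[31, 31] <- 0; rc[31, 31] <- 1
  res <- postprocess(saliency_map(lc, rc), bbox(50, 50, 60, 60))
  expect_true(res$corrected)
  expect_gt(pair_length(res$pair), 0)
})
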