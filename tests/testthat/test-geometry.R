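test_that("caliper circle is the midpoint/half-distance circle", {
  c1 <- circle_from_landmarks(landmark_pair(point(0, 0), point(10, 0)))
  expect_equal(c1$center[["x"]], 5)
  expect_equal(c1$center[["y"]], 0)
  expect_equal(c1$radius, 5)

  c2 <- circle_from_landmarks(landmark_pair(point(10, 20), point(70, 100)))
  expect_equal(unname(c2$center), c(40, 60))
  expect_equal(c2$radius, 50)

  expect_error(landmark_pair(point(3, 3), point(3, 3)), "degenerate")
})

test_that("landmark pairs normalise to canonical left/right order", {
  p <- landmark_pair(point(10, 0), point(0, 0))
  expect_equal(p$left[["x"]], 0)
  expect_equal(p$right[["x"]], 10)
  # vertical pair: tie on x broken by y
  v <- landmark_pair(point(5, 9), point(5, 2))
  expect_equal(v$left[["y"]], 2)
})

test_that("bounding box circumscribes the caliper circle", {
  b <- bbox_from_landmarks(landmark_pair(point(0, 0), point(10, 0)))
  expect_equal(unname(b), c(5, 0, 10, 10))
  b2 <- bbox_from_landmarks(landmark_pair(point(10, 20), point(70, 100)))
  expect_equal(unname(b2), c(40, 60, 100, 100))

  set.seed(11)
  for (k in 1:50) {
    pair <- random_pair()
    b <- bbox_from_landmarks(pair)
    circ <- circle_from_landmarks(pair)
    expect_identical(b[["w"]], b[["h"]])
    # inscribed circle of the square is exactly the caliper circle
    expect_equal(b[["cx"]], circ$center[["x"]], tolerance = 1e-9)
    expect_equal(b[["cy"]], circ$center[["y"]], tolerance = 1e-9)
    expect_equal(b[["w"]] / 2, circ$radius, tolerance = 1e-9)
  }
})

test_that("circle IoU matches the analytic lens area", {
  a <- circle(point(0, 0), 1)
  expect_equal(circle_iou(a, a), 1)
  expect_equal(circle_iou(a, circle(point(5, 0), 1)), 0)
  # unit circles one radius apart: lens = 2*pi/3 - sqrt(3)/2
  lens <- 2 * pi / 3 - sqrt(3) / 2
  expect_equal(circle_iou(a, circle(point(1, 0), 1)),
               lens / (2 * pi - lens), tolerance = 1e-9)
  # nested circles: area ratio
  expect_equal(circle_iou(circle(point(0, 0), 2), circle(point(0.5, 0), 1)),
               1 / 4, tolerance = 1e-9)
})

test_that("circle IoU is symmetric, bounded, and 1 only at coincidence", {
  set.seed(21)
  for (k in 1:25) {
    a <- circle(point(runif(1, 0, 50), runif(1, 0, 50)), runif(1, 1, 20))
    b <- circle(point(runif(1, 0, 50), runif(1, 0, 50)), runif(1, 1, 20))
    i1 <- circle_iou(a, b); i2 <- circle_iou(b, a)
    expect_equal(i1, i2, tolerance = 1e-12)
    expect_gte(i1, 0); expect_lte(i1, 1)
    if (i1 == 1) {
      expect_equal(unname(a$center), unname(b$center))
      expect_equal(a$radius, b$radius)
    }
  }
})

test_that("circle IoU agrees with a rasterization oracle", {
  set.seed(31)
  for (k in 1:10) {
    a <- circle(point(runif(1, 40, 60), runif(1, 40, 60)), runif(1, 10, 30))
    b <- circle(point(runif(1, 40, 60), runif(1, 40, 60)), runif(1, 10, 30))
    expect_equal(circle_iou(a, b), raster_circle_iou(a, b), tolerance = 0.01)
  }
})

test_that("box overlap returns IoU and the GIoU penalty", {
  b <- bbox(5, 5, 10, 10)
  expect_equal(unname(box_overlap(b, b)), c(1, 0))
  # separated unit squares: AC area 3, union 2
  sep <- box_overlap(bbox(0.5, 0.5, 1, 1), bbox(2.5, 0.5, 1, 1))
  expect_equal(unname(sep), c(0, 1 / 3))
  # adjacent unit squares: AC = union
  adj <- box_overlap(bbox(0.5, 0.5, 1, 1), bbox(1.5, 0.5, 1, 1))
  expect_equal(unname(adj), c(0, 0))
  # symmetry
  x <- bbox(3, 4, 6, 2); y <- bbox(5, 5, 3, 7)
  expect_equal(box_overlap(x, y), box_overlap(y, x))
})

test_that("degenerate geometry is rejected", {
  expect_error(bbox(0, 0, 0, 5))
  expect_error(circle(point(0, 0), 0))
  expect_error(cyst_spec(point(0, 0), 1, 2, 0, 0.5))
})
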