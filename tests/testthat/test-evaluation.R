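hpair <- function(x1, x2, y = 0) landmark_pair(point(x1, y), point(x2, y))

test_that("matching keeps only circle IoU above the threshold", {
  p <- hpair(0, 10)
  ms <- match_pairs(list(p), list(p))
  expect_length(ms$matches, 1L)
  expect_equal(ms$matches[[1]]$iou, 1)
  expect_length(ms$unmatched_truth, 0L)
  expect_length(ms$unmatched_pred, 0L)

  far <- match_pairs(list(hpair(0, 10)), list(hpair(100, 110)))
  expect_length(far$matches, 0L)
  expect_equal(far$unmatched_truth, 1L)
  expect_equal(far$unmatched_pred, 1L)
})

test_that("greedy matching picks the strongest assignments first", {
  truth <- list(hpair(0, 20, y = 0), hpair(0, 20, y = 100))
  # pred 1 overlaps truth 1 strongly and truth 2 not at all; pred 2 the
  # reverse; the diagonal matching must win
  pred <- list(hpair(1, 21, y = 0), hpair(2, 22, y = 101))
  ms <- match_pairs(truth, pred)
  expect_length(ms$matches, 2L)
  got <- vapply(ms$matches, function(m) c(m$truth_idx, m$pred_idx),
                numeric(2))
  expect_true(all(got[1, ] == got[2, ]))
})

test_that("greedy matching equals exhaustive matching on small scenes", {
  set.seed(101)
  for (k in 1:50) {
    inst <- random_match_instance()
    ms <- match_pairs(inst$truth, inst$pred)
    expect_equal(length(ms$matches),
                 exhaustive_match_count(inst$truth, inst$pred))
  }
})

test_that("position error uses the optimal point pairing", {
  t <- hpair(0, 10)
  # one point 3-4-5 off, the other exact
  expect_equal(position_error(t, landmark_pair(point(3, 4), point(10, 0))), 5)
  expect_equal(position_error(t, t), 0)
  # swapped annotation order still scores 0 (naive order would give 20)
  swapped <- landmark_pair(point(10, 0), point(0, 0))
  expect_equal(position_error(t, swapped), 0)
  # spacing converts to millimetres
  expect_equal(position_error(t, landmark_pair(point(3, 4), point(10, 0)),
                              spacing = 0.1), 0.5)
})

test_that("diameter length error depends only on the two lengths", {
  t <- hpair(0, 5)
  expect_equal(dle(t, hpair(20, 30)), 5)
  expect_equal(dle(t, t), 0)
  expect_equal(dle(t, hpair(20, 30), spacing = 0.1), 0.5)
  # rigid rotation of the prediction about its midpoint leaves DLE fixed
  set.seed(111)
  p <- random_pair()
  mid <- sonocaliper:::point_midpoint(p$left, p$right)
  for (th in runif(5, 0, 2 * pi)) {
    rot <- function(q) point(
      mid[["x"]] + cos(th) * (q[["x"]] - mid[["x"]]) -
        sin(th) * (q[["y"]] - mid[["y"]]),
      mid[["y"]] + sin(th) * (q[["x"]] - mid[["x"]]) +
        cos(th) * (q[["y"]] - mid[["y"]]))
    pr <- landmark_pair(rot(p$left), rot(p$right))
    expect_equal(dle(hpair(0, 30), pr), dle(hpair(0, 30), p),
                 tolerance = 1e-9)
  }
})

test_that("DLE never exceeds the optimally-paired position error", {
  set.seed(121)
  for (k in 1:50) {
    t <- random_pair(); p <- random_pair()
    expect_lte(dle(t, p), position_error(t, p) + 1e-12)
  }
})

test_that("the report reproduces hand-computed counts and ratios", {
  # 10 truths over 4 images; 8 matched exactly, 2 missed, 2 spurious
  truth <- list(
    img1 = list(hpair(0, 20), hpair(0, 20, y = 60)),
    img2 = list(hpair(10, 40)),
    img3 = list(hpair(0, 30), hpair(50, 90, y = 50), hpair(0, 20, y = 120)),
    img4 = list(hpair(0, 25), hpair(40, 70, y = 40), hpair(0, 30, y = 100),
                hpair(60, 100, y = 110)))
  pred <- truth
  pred$img1[[2]] <- hpair(300, 320)        # one miss + one spurious
  pred$img3[[3]] <- hpair(300, 320, y = 5) # another
  report <- evaluate(truth, pred)
  expect_equal(report$tp, 8L)
  expect_equal(report$fp, 2L)
  expect_equal(report$fn, 2L)
  expect_equal(report$precision, 0.8)
  expect_equal(report$recall, 0.8)
  expect_length(report$position_errors, 8L)
  expect_equal(report$mean_position_error, 0)
  expect_equal(report$mean_dle, 0)
})

test_that("perfect predictions give unit precision/recall and zero error", {
  set.seed(131)
  truth <- list(a = list(random_pair()), b = list(random_pair(),
                                                  random_pair(60, 120)))
  report <- evaluate(truth, truth, spacing = 0.1)
  expect_equal(report$precision, 1)
  expect_equal(report$recall, 1)
  expect_true(all(report$position_errors == 0))
  expect_true(all(report$dles == 0))
})

test_that("evaluation ignores the order of predictions within an image", {
  set.seed(141)
  truth <- list(img = list(hpair(0, 20), hpair(0, 24, y = 60),
                           hpair(10, 36, y = 120)))
  pred <- list(img = list(hpair(1, 21), hpair(1, 25, y = 60),
                          hpair(11, 37, y = 120)))
  r1 <- evaluate(truth, pred)
  r2 <- evaluate(truth, list(img = rev(pred$img)))
  expect_equal(r1$tp, r2$tp)
  expect_equal(sort(r1$position_errors), sort(r2$position_errors))
  expect_error(evaluate(truth, list(other = pred$img)), "ids")
})

test_that("reports export to CSV and JSON", {
  truth <- list(img = list(hpair(0, 20)))
  report <- evaluate(truth, truth, spacing = 0.1)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  export_report(report, csv_path = csv, json_path = js)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$circle_iou, 1)
  summ <- jsonlite::read_json(js)
  expect_equal(summ$tp, 1L)
  expect_equal(summ$precision, 1)
  expect_equal(summ$spacing, 0.1)
})
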