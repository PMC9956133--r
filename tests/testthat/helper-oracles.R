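# Independent oracles used by the unit and acceptance tests.

# Rasterized circle IoU: count pixels inside each disk on a fine grid.
raster_circle_iou <- function(a, b, step = 0.25) {
  x0 <- min(a$center[["x"]] - a$radius, b$center[["x"]] - b$radius)
  x1 <- max(a$center[["x"]] + a$radius, b$center[["x"]] + b$radius)
  y0 <- min(a$center[["y"]] - a$radius, b$center[["y"]] - b$radius)
  y1 <- max(a$center[["y"]] + a$radius, b$center[["y"]] + b$radius)
  xs <- seq(x0, x1, by = step)
  ys <- seq(y0, y1, by = step)
  da <- outer((ys - a$center[["y"]])^2, (xs - a$center[["x"]])^2, `+`) <=
    a$radius^2
  db <- outer((ys - b$center[["y"]])^2, (xs - b$center[["x"]])^2, `+`) <=
    b$radius^2
  inter <- sum(da & db)
  union <- sum(da | db)
  if (union == 0) 0 else inter / union
}

# Exhaustive optimal one-to-one matching maximising total IoU above the
# threshold (enumerates all assignments; fine for <= 4 pairs).
exhaustive_match_count <- function(truth, pred, iou_threshold = 0.5) {
  nt <- length(truth); np <- length(pred)
  if (nt == 0L || np == 0L) return(0L)
  tc <- lapply(truth, circle_from_landmarks)
  pc <- lapply(pred, circle_from_landmarks)
  iou <- matrix(0, nt, np)
  for (i in seq_len(nt))
    for (j in seq_len(np)) iou[i, j] <- circle_iou(tc[[i]], pc[[j]])
  best <- 0L
  # enumerate injective assignments truth -> pred (or no match, index 0)
  assign_next <- function(i, used, count) {
    if (i > nt) { best <<- max(best, count); return(invisible(NULL)) }
    assign_next(i + 1L, used, count)  # truth i unmatched
    for (j in seq_len(np)) {
      if (!used[j] && iou[i, j] > iou_threshold) {
        used[j] <- TRUE
        assign_next(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  assign_next(1L, logical(np), 0L)
  best
}

# Random non-degenerate landmark pair inside a box
random_pair <- function(lo = 0, hi = 100, min_dist = 5) {
  repeat {
    p1 <- point(runif(1, lo, hi), runif(1, lo, hi))
    p2 <- point(runif(1, lo, hi), runif(1, lo, hi))
    if (point_distance(p1, p2) >= min_dist) return(landmark_pair(p1, p2))
  }
}

# A random scene-like matching instance: truths are landmark pairs whose
# caliper circles do not overlap (the scene invariant); predictions are
# shifted copies of truths plus spurious extras.
random_match_instance <- function(max_pairs = 4) {
  nt <- sample(0:max_pairs, 1)
  truth <- list()
  tries <- 0
  while (length(truth) < nt && tries < 100) {
    tries <- tries + 1
    cand <- random_pair(0, 200, min_dist = 10)
    cc <- circle_from_landmarks(cand)
    ok <- all(vapply(truth, function(t) {
      tc <- circle_from_landmarks(t)
      point_distance(tc$center, cc$center) > tc$radius + cc$radius
    }, logical(1)))
    if (ok) truth[[length(truth) + 1]] <- cand
  }
  np <- sample(0:max_pairs, 1)
  pred <- list()
  for (k in seq_len(np)) {
    pred[[k]] <- if (length(truth) > 0 && runif(1) < 0.7) {
      b <- truth[[sample(length(truth), 1)]]
      d <- runif(2, -4, 4)
      landmark_pair(point(b$left[["x"]] + d[1], b$left[["y"]] + d[2]),
                    point(b$right[["x"]] + d[1], b$right[["y"]] + d[2]))
    } else random_pair(0, 200, min_dist = 10)
  }
  list(truth = truth, pred = pred)
}

# Shared tiny training dataset for model tests (built once per run)
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "sonocaliper-tiny-ds")
      if (!dir.exists(dir)) generate_dataset(10, dir, seed = 5)
      cache <<- load_dataset(dir)
    }
    cache
  }
})
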