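# Synthetic B-mode phantom generator.  A scene is a smooth tissue
# intensity field multiplied by smoothed Rayleigh speckle, with 0-3
# non-overlapping anechoic (dark) elliptical cysts.  Ground truth per
# cyst: the landmark pair at the major-axis endpoints and the square
# bounding box circumscribing the caliper circle.  Everything is
# deterministic given the scene seed, so scenes can be re-rendered
# bit-exactly from the dataset manifest.

#' Specification of one synthetic cyst
#'
#' @param center `caliper_point`: cyst centre in pixels.
#' @param semi_major,semi_minor Ellipse semi-axes in pixels
#'   (`semi_major >= semi_minor > 0`).
#' @param angle Major-axis angle in radians (x-axis positive, y down).
#' @param darkness Interior contrast factor in `(0, 1)`: interior
#'   intensity = background intensity times `darkness`.
#' @return An object of class `cyst_spec`.
#' @export
cyst_spec <- function(center, semi_major, semi_minor, angle, darkness) {
  center <- as_point(center)
  stopifnot(semi_major >= semi_minor, semi_minor > 0,
            darkness > 0, darkness < 1)
  structure(list(center = center, semi_major = as.numeric(semi_major),
                 semi_minor = as.numeric(semi_minor),
                 angle = as.numeric(angle), darkness = as.numeric(darkness)),
            class = "cyst_spec")
}

cyst_landmarks <- function(cs) {
  dx <- cs$semi_major * cos(cs$angle); dy <- cs$semi_major * sin(cs$angle)
  landmark_pair(point(cs$center[["x"]] - dx, cs$center[["y"]] - dy),
                point(cs$center[["x"]] + dx, cs$center[["y"]] + dy))
}

#' Specification of a synthetic scene
#'
#' @param size Image side length in pixels.
#' @param pixel_spacing mm per pixel (default 0.1).
#' @param cysts List of [cyst_spec()] objects; enclosing caliper circles
#'   must not overlap and every cyst must lie fully inside the image.
#' @param seed Integer seed for background and speckle.
#' @param background Mean tissue intensity (default 150).
#' @param speckle_sd Standard deviation of the smoothed multiplicative
#'   speckle field (default 0.25; 0 disables speckle).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(size = 128L, pixel_spacing = 0.1, cysts = list(),
                       seed = 1L, background = 150, speckle_sd = 0.25) {
  stopifnot(size >= 16, pixel_spacing > 0, speckle_sd >= 0)
  structure(list(size = as.integer(size), pixel_spacing = pixel_spacing,
                 cysts = cysts, seed = as.integer(seed),
                 background = background, speckle_sd = speckle_sd),
            class = "scene_spec")
}

check_scene <- function(spec) {
  n <- length(spec$cysts)
  for (cs in spec$cysts) {
    ext <- cs$semi_major
    if (cs$center[["x"]] - ext < 0 || cs$center[["x"]] + ext > spec$size - 1 ||
        cs$center[["y"]] - ext < 0 || cs$center[["y"]] + ext > spec$size - 1)
      stop("cyst extends outside the image")
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        a <- spec$cysts[[i]]; b <- spec$cysts[[j]]
        d <- point_distance(a$center, b$center)
        if (d <= a$semi_major + b$semi_major)
          stop("cysts overlap: enclosing caliper circles intersect")
      }
    }
  }
  invisible(spec)
}

# smooth low-frequency field: bilinear upsample of a coarse random grid
smooth_field <- function(size, n_knots, amplitude) {
  g <- matrix(runif(n_knots^2, -amplitude, amplitude), n_knots, n_knots)
  pos <- seq(0, n_knots - 1, length.out = size)
  bilinear_sample(g, pos, pos)
}

#' Render a synthetic ultrasound scene
#'
#' Background = smooth tissue intensity times smoothed Rayleigh
#' multiplicative speckle; each cyst darkens the interior by its
#' `darkness` factor with a soft ~2 px boundary.  Deterministic given the
#' scene seed.
#'
#' @param spec A [scene_spec()].
#' @return A list with `image` (an `ultrasound_image`) and `annotations`
#'   (list of [cyst_annotation()], one per cyst).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  check_scene(spec)
  old <- .Random.seed_save(spec$seed)
  on.exit(.Random.seed_restore(old))
  s <- spec$size
  tissue <- spec$background * (1 + smooth_field(s, 5L, 0.15))
  # cyst interiors darken the echo intensity before speckle is applied
  xs <- matrix(rep(0:(s - 1), each = s), s, s)    # col index = x
  ys <- matrix(rep(0:(s - 1), times = s), s, s)   # row index = y
  for (cs in spec$cysts) {
    dx <- xs - cs$center[["x"]]; dy <- ys - cs$center[["y"]]
    u <- (dx * cos(cs$angle) + dy * sin(cs$angle)) / cs$semi_major
    v <- (-dx * sin(cs$angle) + dy * cos(cs$angle)) / cs$semi_minor
    f <- sqrt(u^2 + v^2)
    # signed distance to the ellipse edge, approximated in pixels
    dpx <- (1 - f) * cs$semi_minor
    alpha <- pmin(pmax(dpx / 2 + 0.5, 0), 1)   # ~2 px soft boundary
    tissue <- tissue * (1 - alpha * (1 - cs$darkness))
  }
  if (spec$speckle_sd > 0) {
    # Rayleigh multiplicative speckle, unit mean, lightly smoothed
    ray <- matrix(sqrt(-2 * log(runif(s * s))), s, s) / sqrt(pi / 2)
    k <- matrix(1, 3, 3) / 9
    ray <- convolve2_same(ray, k)
    speckle <- 1 + spec$speckle_sd * (ray - mean(ray)) / stats::sd(ray)
    tissue <- tissue * pmax(speckle, 0)
  }
  img <- ultrasound_image(pmin(pmax(round(tissue), 0), 255),
                          pixel_spacing = spec$pixel_spacing)
  anns <- lapply(spec$cysts, function(cs) cyst_annotation(cyst_landmarks(cs)))
  list(image = img, annotations = anns)
}

# 2-D same-size convolution with edge replication (small kernels only)
convolve2_same <- function(m, k) {
  kr <- (nrow(k) - 1L) %/% 2L; kc <- (ncol(k) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(rep(1L, kr), seq_len(nr), rep(nr, kr)),
           c(rep(1L, kc), seq_len(nc), rep(nc, kc))]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      out <- out + k[i, j] * pad[(i - 1L) + seq_len(nr), (j - 1L) + seq_len(nc)]
    }
  }
  out
}

#' Default random-scene configuration
#'
#' Ranges from which [generate_dataset()] draws cyst geometry: semi-major
#' axis 10-24 px on a 128 px image, axis ratio 0.55-0.8, any orientation,
#' interior contrast 0.15-0.45, 1-2 cysts per image.  The axis-ratio
#' ceiling stays below 1 so that every cyst has an identifiable longest
#' diameter: for a near-circular cyst the major-axis endpoints — and with
#' them the landmark ground truth — are rotationally ambiguous.
#'
#' @param size Image side (default 128).
#' @param pixel_spacing mm per pixel (default 0.1).
#' @param n_cysts_range Integer range of cysts per image.
#' @param semi_major_range,axis_ratio_range,darkness_range Uniform draw
#'   ranges for the ellipse geometry and contrast.
#' @param background,speckle_sd Passed to [scene_spec()].
#' @param min_separation Extra margin (px) between enclosing circles.
#' @return A list of class `dataset_config`.
#' @export
dataset_config <- function(size = 128L, pixel_spacing = 0.1,
                           n_cysts_range = c(1L, 2L),
                           semi_major_range = c(10, 24),
                           axis_ratio_range = c(0.55, 0.8),
                           darkness_range = c(0.15, 0.45),
                           background = 150, speckle_sd = 0.25,
                           min_separation = 8) {
  structure(list(size = as.integer(size), pixel_spacing = pixel_spacing,
                 n_cysts_range = as.integer(n_cysts_range),
                 semi_major_range = semi_major_range,
                 axis_ratio_range = axis_ratio_range,
                 darkness_range = darkness_range, background = background,
                 speckle_sd = speckle_sd, min_separation = min_separation),
            class = "dataset_config")
}

# rejection-sample a valid random scene spec
random_scene_spec <- function(config, seed) {
  old <- .Random.seed_save(seed)
  on.exit(.Random.seed_restore(old))
  n <- sample(seq(config$n_cysts_range[1L], config$n_cysts_range[2L]), 1L)
  cysts <- list()
  tries <- 0L
  while (length(cysts) < n && tries < 200L) {
    tries <- tries + 1L
    a <- runif(1, config$semi_major_range[1L], config$semi_major_range[2L])
    b <- a * runif(1, config$axis_ratio_range[1L], config$axis_ratio_range[2L])
    margin <- a + 2
    ctr <- point(runif(1, margin, config$size - 1 - margin),
                 runif(1, margin, config$size - 1 - margin))
    ok <- TRUE
    for (cs in cysts) {
      if (point_distance(ctr, cs$center) <=
          a + cs$semi_major + config$min_separation) { ok <- FALSE; break }
    }
    if (!ok) next
    cysts[[length(cysts) + 1L]] <-
      cyst_spec(ctr, a, b, runif(1, 0, pi),
                runif(1, config$darkness_range[1L], config$darkness_range[2L]))
  }
  scene_spec(size = config$size, pixel_spacing = config$pixel_spacing,
             cysts = cysts, seed = seed + 500000L,
             background = config$background, speckle_sd = config$speckle_sd)
}

scene_spec_to_list <- function(sp) {
  list(size = sp$size, pixel_spacing = sp$pixel_spacing, seed = sp$seed,
       background = sp$background, speckle_sd = sp$speckle_sd,
       cysts = lapply(sp$cysts, function(cs)
         list(cx = cs$center[["x"]], cy = cs$center[["y"]],
              semi_major = cs$semi_major, semi_minor = cs$semi_minor,
              angle = cs$angle, darkness = cs$darkness)))
}

scene_spec_from_list <- function(l) {
  scene_spec(size = l$size, pixel_spacing = l$pixel_spacing,
             cysts = lapply(l$cysts, function(cs)
               cyst_spec(point(cs$cx, cs$cy), cs$semi_major, cs$semi_minor,
                         cs$angle, cs$darkness)),
             seed = l$seed, background = l$background,
             speckle_sd = l$speckle_sd)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` PNG images with per-image annotation text files and a JSON
#' manifest recording every scene specification (so the dataset can be
#' re-rendered bit-exactly).
#'
#' @param n Number of images (>= 1).
#' @param out_dir Output directory (created if missing).
#' @param config A [dataset_config()].
#' @param seed Integer master seed; scene `i` uses `seed + i`.
#' @return The manifest, invisibly (a list with `config`, `seed`,
#'   `scenes`, `images`, `annotations` file names).
#' @export
generate_dataset <- function(n, out_dir, config = dataset_config(),
                             seed = 1L) {
  stopifnot(n >= 1)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  scenes <- lapply(seq_len(n), function(i) random_scene_spec(config, seed + i))
  img_files <- sprintf("img_%04d.png", seq_len(n))
  ann_files <- sprintf("img_%04d.txt", seq_len(n))
  for (i in seq_len(n)) {
    sc <- render_scene(scenes[[i]])
    write_image(sc$image, file.path(out_dir, img_files[[i]]))
    write_annotations(sc$annotations, file.path(out_dir, ann_files[[i]]))
  }
  manifest <- list(seed = seed, pixel_spacing = config$pixel_spacing,
                   images = img_files, annotations = ann_files,
                   scenes = lapply(scenes, scene_spec_to_list))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a dataset directory generated by [generate_dataset()]
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @return A list with `images` (list of `ultrasound_image`),
#'   `annotations` (per-image annotation lists, names = image file names)
#'   and `pixel_spacing`.
#' @export
load_dataset <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir)
  mf <- jsonlite::read_json(mf_path)
  spacing <- as.numeric(mf$pixel_spacing)
  images <- lapply(mf$images, function(f)
    read_image(file.path(dir, f), pixel_spacing = spacing))
  annotations <- lapply(mf$annotations, function(f)
    read_annotations(file.path(dir, f)))
  names(images) <- names(annotations) <- unlist(mf$images)
  list(images = images, annotations = annotations, pixel_spacing = spacing)
}

#' Re-render a dataset from its manifest
#'
#' @param manifest_path Path to a `manifest.json`.
#' @return A list of rendered scenes (`image` + `annotations`), in
#'   manifest order.
#' @export
render_from_manifest <- function(manifest_path) {
  mf <- jsonlite::read_json(manifest_path)
  lapply(mf$scenes, function(l) render_scene(scene_spec_from_list(l)))
}
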