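# Synthetic image benchmarks.
#
# The cross-window task generates labelled grayscale images whose class
# depends on the *relationship* between two oriented motifs stamped in
# horizontally adjacent attention windows: class 1 iff the motifs share an
# orientation. Each motif's own orientation is drawn uniformly, so no single
# window carries any class information — a classifier restricted to
# within-window content sits at chance, which is exactly the dependency
# structure the K2 pathway is meant to supply. The blob task is a linearly
# separable smoke test (class = blob intensity).

#' Synthetic task specification
#'
#' @param n_samples Number of images to generate.
#' @param image_hw Image size in pixels (default 56 x 56, matching the mini
#'   models; use 224 x 224 for Tiny-scale runs).
#' @param n_classes Number of classes (2).
#' @param motif_size Motif edge length in pixels; must fit inside one window.
#' @param noise_sd Standard deviation of the additive Gaussian pixel noise.
#' @param task `"cross_window"` or `"blob"`.
#' @param seed Integer seed; generation is bit-reproducible for a fixed seed.
#' @param window_px Attention-window extent in pixels (window M times patch
#'   size; 28 for the default M = 7, patch 4 geometry).
#' @param shift_px Cyclic-shift magnitude of the intended consumer model in
#'   pixels (`floor(M/2)` tokens times patch size; 12 for the default
#'   geometry). The second motif is stamped at exactly this displacement from
#'   the first.
#' @return List of class `"synth_spec"`.
#' @export
synth_spec <- function(n_samples, image_hw = c(56L, 56L), n_classes = 2L,
                       motif_size = 5L, noise_sd = 0.1,
                       task = c("cross_window", "blob"), seed = 0L,
                       window_px = 28L, shift_px = 12L) {
  task <- match.arg(task)
  if (n_samples < 0L) stop("n_samples must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_classes != 2L) stop("only 2-class tasks are implemented", call. = FALSE)
  if (motif_size > window_px) {
    stop(sprintf("motif_size %d exceeds the %d-pixel window", motif_size, window_px),
         call. = FALSE)
  }
  if (any(image_hw %% window_px != 0L) || image_hw[2] %/% window_px < 2L) {
    stop("image sides must be multiples of window_px with >= 2 windows across",
         call. = FALSE)
  }
  if (task == "cross_window" &&
      (shift_px < motif_size + 2L || shift_px > window_px - motif_size - 2L)) {
    stop(sprintf(
      "shift_px = %d incompatible with motif_size = %d in a %d-pixel window",
      shift_px, motif_size, window_px), call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples), image_hw = as.integer(image_hw),
                 n_classes = 2L, motif_size = as.integer(motif_size),
                 noise_sd = noise_sd, task = task, seed = as.integer(seed),
                 window_px = as.integer(window_px), shift_px = as.integer(shift_px)),
            class = "synth_spec")
}

# Balanced 0/1 labels (within one for odd n), order shuffled by the current
# RNG stream.
#' @noRd
balanced_labels <- function(n) {
  if (n == 0L) return(integer(0))
  base <- rep(c(0L, 1L), length.out = n)
  base[sample.int(n)]
}

#' @noRd
motif_pattern <- function(m, orientation) {
  pat <- diag(m)
  if (orientation == 1L) pat <- pat[, m:1, drop = FALSE]
  pat
}

# Stamp positions for the two motifs. The left motif sits near the right edge
# of the left window; the right motif is displaced from it by exactly
# (shift_px, shift_px), which places it inside the horizontally adjacent
# window. A cyclic shift of that magnitude therefore maps the right motif
# onto the left motif's own positions, so the Q.K2^T score term compares the
# two orientations directly — the dependency structure the second Key matrix
# is designed to capture.
#' @noRd
motif_anchors <- function(spec) {
  wp <- spec$window_px
  m <- spec$motif_size
  s <- spec$shift_px
  nwr <- spec$image_hw[1] %/% wp
  nwc <- spec$image_hw[2] %/% wp
  wr <- (nwr + 1L) %/% 2L          # window row of both motifs
  wcl <- max(1L, nwc %/% 2L)       # left window of the adjacent pair
  r0 <- (wr - 1L) * wp + 3L                      # near the window top
  cl <- (wcl - 1L) * wp + (wp - m - 1L)          # near the right edge
  list(rows_left = r0:(r0 + m - 1L), cols_left = cl:(cl + m - 1L),
       rows_right = (r0 + s):(r0 + s + m - 1L),
       cols_right = (cl + s):(cl + s + m - 1L))
}

#' Generate the cross-window benchmark
#'
#' Two oriented motifs (a diagonal or anti-diagonal bar) are stamped in
#' horizontally adjacent attention windows; the image is class 1 iff the two
#' orientations match. Labels are balanced to within one; pixel noise is
#' additive Gaussian, clipped to `[0, 1]`.
#'
#' @param spec A [synth_spec()] with `task = "cross_window"`.
#' @return List with `images` (n x h x w array in `[0, 1]`), `labels`
#'   (integer 0/1), and `meta` (`data.frame` of the stamped orientations).
#' @export
gen_cross_window <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (spec$task != "cross_window") stop("spec$task must be 'cross_window'", call. = FALSE)
  n <- spec$n_samples
  h <- spec$image_hw[1]; w <- spec$image_hw[2]
  anch <- motif_anchors(spec)
  with_seed(spec$seed, {
    labels <- balanced_labels(n)
    o1 <- if (n > 0L) sample(c(0L, 1L), n, replace = TRUE) else integer(0)
    o2 <- ifelse(labels == 1L, o1, 1L - o1)
    images <- array(0, dim = c(n, h, w))
    for (i in seq_len(n)) {
      img <- matrix(0.1, h, w)
      img[anch$rows_left, anch$cols_left] <- img[anch$rows_left, anch$cols_left] +
        motif_pattern(spec$motif_size, o1[i]) * 0.85
      img[anch$rows_right, anch$cols_right] <- img[anch$rows_right, anch$cols_right] +
        motif_pattern(spec$motif_size, o2[i]) * 0.85
      if (spec$noise_sd > 0) {
        img <- img + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
      }
      images[i, , ] <- pmin(pmax(img, 0), 1)
    }
    list(images = images, labels = labels,
         meta = data.frame(orient_left = o1, orient_right = o2))
  })
}

#' Generate the blob smoke-test benchmark
#'
#' A single centred disk whose mean intensity determines the class (0.35 for
#' class 0, 0.65 for class 1): linearly separable by a global mean threshold
#' when `noise_sd = 0`.
#'
#' @param spec A [synth_spec()] with `task = "blob"`.
#' @return As [gen_cross_window()]; `meta` records each blob intensity.
#' @export
gen_blob <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  if (spec$task != "blob") stop("spec$task must be 'blob'", call. = FALSE)
  n <- spec$n_samples
  h <- spec$image_hw[1]; w <- spec$image_hw[2]
  rr <- outer(seq_len(h) - (h + 1) / 2, rep(1, w))
  cc <- outer(rep(1, h), seq_len(w) - (w + 1) / 2)
  disk <- (rr^2 + cc^2) <= (min(h, w) / 4)^2
  with_seed(spec$seed, {
    labels <- balanced_labels(n)
    intensity <- ifelse(labels == 1L, 0.65, 0.35)
    images <- array(0, dim = c(n, h, w))
    for (i in seq_len(n)) {
      img <- matrix(0.1, h, w)
      img[disk] <- intensity[i]
      if (spec$noise_sd > 0) {
        img <- img + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
      }
      images[i, , ] <- pmin(pmax(img, 0), 1)
    }
    list(images = images, labels = labels,
         meta = data.frame(intensity = if (n > 0L) intensity else numeric(0)))
  })
}

#' Generate a dataset from a task specification
#'
#' Dispatches to [gen_cross_window()] or [gen_blob()].
#'
#' @param spec A [synth_spec()].
#' @return See the task generators.
#' @export
generate_dataset <- function(spec) {
  switch(spec$task, cross_window = gen_cross_window(spec), blob = gen_blob(spec))
}

#' 6:2:2 train/validation/test split
#'
#' After a seeded shuffle, the first `floor(0.6 n)` indices form the training
#' set, the next `floor(0.2 n)` the validation set, and the remainder the test
#' set; the parts are disjoint and exhaustive.
#'
#' @param n_items Number of items to split.
#' @param seed Integer seed for the shuffle.
#' @return List with integer index vectors `train`, `val`, `test` and the
#'   `ratios` field `(0.6, 0.2, 0.2)`.
#' @export
split_622 <- function(n_items, seed = 0L) {
  if (n_items < 0L) stop("n_items must be >= 0", call. = FALSE)
  n <- as.integer(n_items)
  idx <- if (n > 0L) with_seed(seed, sample.int(n)) else integer(0)
  n_train <- floor(0.6 * n)
  n_val <- floor(0.2 * n)
  list(train = idx[seq_len(n_train)],
       val = idx[n_train + seq_len(n_val)],
       test = idx[setdiff(seq_len(n), seq_len(n_train + n_val))],
       ratios = c(0.6, 0.2, 0.2))
}

#' Write a dataset as one-directory-per-class PNG folders
#'
#' Writes `class_<k>/img_<i>.png` files plus a `manifest.csv`
#' (filename, label, split).
#'
#' @param ds Dataset list from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param split Optional [split_622()] result used to fill the manifest's
#'   split column.
#' @return Path of the manifest file, invisibly.
#' @export
write_image_folder <- function(ds, dir, split = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(ds$labels)
  split_of <- rep("train", n)
  if (!is.null(split)) {
    split_of[split$val] <- "val"
    split_of[split$test] <- "test"
  }
  files <- character(n)
  for (i in seq_len(n)) {
    cls_dir <- file.path(dir, sprintf("class_%d", ds$labels[i]))
    dir.create(cls_dir, showWarnings = FALSE)
    files[i] <- file.path(sprintf("class_%d", ds$labels[i]),
                          sprintf("img_%05d.png", i))
    png::writePNG(ds$images[i, , ], file.path(dir, files[i]))
  }
  manifest <- data.frame(filename = files, label = ds$labels, split = split_of)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a one-directory-per-class image folder
#'
#' Reads every PNG under `class_*` subdirectories; color images are averaged
#' to grayscale.
#'
#' @param dir Dataset directory written by [write_image_folder()] or arranged
#'   in the same layout.
#' @return List with `images` (n x h x w array) and `labels`.
#' @export
read_image_folder <- function(dir) {
  cls_dirs <- sort(list.dirs(dir, recursive = FALSE))
  files <- character(0); labels <- integer(0)
  for (cd in cls_dirs) {
    fs <- sort(list.files(cd, pattern = "\\.png$", full.names = TRUE))
    files <- c(files, fs)
    lab <- as.integer(sub(".*_([0-9]+)$", "\\1", basename(cd)))
    labels <- c(labels, rep(lab, length(fs)))
  }
  if (length(files) == 0L) stop(sprintf("no class_*/...png files under %s", dir), call. = FALSE)
  imgs <- lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 3L) a <- apply(a[, , 1:3, drop = FALSE], c(1, 2), mean)
    a
  })
  d <- dim(imgs[[1]])
  images <- array(0, dim = c(length(imgs), d[1], d[2]))
  for (i in seq_along(imgs)) images[i, , ] <- imgs[[i]]
  list(images = images, labels = labels)
}
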