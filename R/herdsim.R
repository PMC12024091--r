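# Synthetic herd generator and preprocessing pipeline.
#
# Each identity is a procedural black/white coat pattern (a band-limited
# Gaussian random field thresholded at a quantile); frames place the pattern
# on an elliptical body over a textured floor, under per-frame viewpoint
# perspective, rotation/translation jitter and lighting gain.  The
# preprocessing ops mirror a field protocol: every-kth frame subsampling,
# SSIM-based deduplication against the last kept frame, a minimum-count
# identity filter, and stratified 7:2:1 splitting.

# evaluate code under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# periodic Gaussian smoothing of a square white-noise field via FFT
smooth_field <- function(z, sigma) {
  n <- nrow(z)
  d <- c(0:(n %/% 2), -((n - (n %/% 2 + 1)):1))  # wrapped distances
  g <- exp(-d^2 / (2 * sigma^2))
  kern <- outer(g, g)
  kern <- kern / sum(kern)
  Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) / n^2
}

#' Generate a procedural coat pattern for one identity
#'
#' Draws a seeded white-noise field, smooths it to patches of the requested
#' scale, and thresholds at the quantile that yields the requested white
#' fraction.  Regeneration from the same arguments is bit-identical.
#'
#' @param seed Integer seed.
#' @param patch_scale Patch size parameter in pattern pixels (> 0);
#'   larger values give larger coat patches.
#' @param white_fraction Target fraction of white pixels, in (0.05, 0.95).
#' @param res Pattern resolution (default 96).
#' @param id Optional identity label stored with the pattern.
#' @return An `identity_pattern` list with the binary `pattern` matrix
#'   (1 = white patch).
#' @export
generate_pattern <- function(seed, patch_scale = 10, white_fraction = 0.4,
                             res = 96L, id = NULL) {
  if (patch_scale <= 0) stop("patch_scale must be positive", call. = FALSE)
  if (white_fraction <= 0.05 || white_fraction >= 0.95) {
    stop("white_fraction must lie in (0.05, 0.95), got ", white_fraction,
         call. = FALSE)
  }
  z <- with_seed(seed, matrix(stats::rnorm(res * res), res, res))
  f <- smooth_field(z, patch_scale)
  thr <- stats::quantile(f, 1 - white_fraction, names = FALSE)
  structure(list(id = id %||% sprintf("id%06d", seed), seed = seed,
                 pattern = (f > thr) + 0, patch_scale = patch_scale,
                 white_fraction = white_fraction),
            class = "identity_pattern")
}

# output -> source homography for each viewpoint: an anisotropic
# foreshortening scale (the dominant effect of an oblique camera) combined
# with a mild perspective term for the trapezoidal look.  The scale keeps
# the local Jacobian above 1 over the whole body, so oblique views strictly
# shrink the visible body area relative to the top view.
view_homography <- function(view, size) {
  cx <- (size + 1) / 2
  compose <- function(sx, sy, px, py) {
    tm <- rbind(c(1, 0, cx), c(0, 1, cx), c(0, 0, 1))
    ti <- rbind(c(1, 0, -cx), c(0, 1, -cx), c(0, 0, 1))
    sc <- diag(c(1 / sx, 1 / sy, 1))
    pp <- rbind(c(1, 0, 0), c(0, 1, 0), c(px, py, 1))
    tm %*% sc %*% pp %*% ti
  }
  switch(view,
    top = diag(3),
    `oblique-left` = compose(0.85, 1, 0.006, 0),
    `oblique-right` = compose(0.85, 1, -0.006, 0),
    rear = compose(1, 0.85, 0, 0.006),
    stop("unknown view '", view, "'", call. = FALSE))
}

PATTERN_WHITE <- 0.88
PATTERN_BLACK <- 0.10

#' Render a synthetic back view of one identity
#'
#' Places the coat pattern on an elliptical body over a seeded floor
#' texture, applies the view's perspective warp plus (optionally) small
#' seeded rotation/translation jitter, and scales brightness by
#' `lighting_gain`.
#'
#' @param p An [generate_pattern()] result.
#' @param view One of `"top"`, `"oblique-left"`, `"oblique-right"`,
#'   `"rear"`.
#' @param lighting_gain Brightness multiplier (clipped to `[0, 1]` after).
#' @param seed Integer seed for the floor texture and jitter.
#' @param size Output image side length (default 64).
#' @param jitter Apply seeded rotation (+-10 degrees) and translation
#'   (+-3 px) of the body (default `TRUE`).
#' @return A `cow_sample` list: `image` (size x size x 3 in `[0, 1]`),
#'   `label`, `view`, `body_frac` (fraction of pixels on the body) and
#'   `provenance`.
#' @export
render_view <- function(p, view = "top", lighting_gain = 1, seed = 1L,
                        size = 64L, jitter = TRUE) {
  hinv <- view_homography(view, size)
  rng <- with_seed(seed, list(
    bg = matrix(stats::rnorm(size * size), size),
    theta = if (jitter) stats::runif(1, -10, 10) * pi / 180 else 0,
    shift = if (jitter) stats::runif(2, -3, 3) else c(0, 0)))
  # floor texture (camera-side; does not warp with the animal)
  bgf <- smooth_field(rng$bg, 3)
  bgf <- bgf / max(abs(bgf), 1e-9)
  img <- array(0, c(size, size, 3))
  base <- c(0.38, 0.33, 0.27)
  for (ch in 1:3) img[, , ch] <- base[ch] + 0.10 * bgf
  theta <- rng$theta
  shift <- rng$shift
  # inverse map every output pixel through the view homography
  cx <- (size + 1) / 2
  grid_x <- matrix(rep(seq_len(size), each = size), size)   # column coord
  grid_y <- matrix(rep(seq_len(size), size), size)          # row coord
  w <- hinv[3, 1] * grid_x + hinv[3, 2] * grid_y + hinv[3, 3]
  xs <- (hinv[1, 1] * grid_x + hinv[1, 2] * grid_y + hinv[1, 3]) / w
  ys <- (hinv[2, 1] * grid_x + hinv[2, 2] * grid_y + hinv[2, 3]) / w
  # body frame: undo jitter rotation/translation about the center
  xr <- cos(theta) * (xs - cx - shift[1]) + sin(theta) * (ys - cx - shift[2])
  yr <- -sin(theta) * (xs - cx - shift[1]) + cos(theta) * (ys - cx - shift[2])
  sx <- 0.30 * size
  sy <- 0.44 * size
  inside <- (xr / sx)^2 + (yr / sy)^2 <= 1
  res <- nrow(p$pattern)
  px <- pmin(pmax(round((xr / sx + 1) / 2 * (res - 1) + 1), 1), res)
  py <- pmin(pmax(round((yr / sy + 1) / 2 * (res - 1) + 1), 1), res)
  val <- ifelse(p$pattern[cbind(as.vector(py), as.vector(px))] > 0,
                PATTERN_WHITE, PATTERN_BLACK)
  for (ch in 1:3) {
    sl <- img[, , ch]
    sl[inside] <- val[inside]
    img[, , ch] <- sl
  }
  img <- pmin(pmax(img * lighting_gain, 0), 1)
  structure(list(image = img, label = p$id, view = view,
                 body_frac = mean(inside),
                 provenance = list(seed = seed, lighting_gain = lighting_gain,
                                   theta = theta, shift = shift)),
            class = "cow_sample")
}

#' Augmentation configuration
#'
#' Defaults follow the training-time augmentation protocol: random
#' horizontal/vertical flips, small rotations, additive Gaussian noise, and
#' a small occluding square.
#'
#' @param p_hflip,p_vflip Flip probabilities (default 0.5 each).
#' @param rotation_range Maximum absolute rotation in degrees (default 15).
#' @param noise_sd Gaussian noise standard deviation (default 0.02).
#' @param occlusion_size Integer range `c(min, max)` of the occluder side in
#'   pixels (default `c(4, 8)`, sized for the default 48-pixel renders).
#' @param occlusion_fill Gray fill value of the occluder (default 0.13).
#' @param p_occlusion Probability of applying the occluder (default 0.5).
#' @return A plain list of settings.
#' @export
augment_config <- function(p_hflip = 0.5, p_vflip = 0.5, rotation_range = 15,
                           noise_sd = 0.02, occlusion_size = c(4L, 8L),
                           occlusion_fill = 0.13, p_occlusion = 0.5) {
  list(p_hflip = p_hflip, p_vflip = p_vflip, rotation_range = rotation_range,
       noise_sd = noise_sd, occlusion_size = as.integer(occlusion_size),
       occlusion_fill = occlusion_fill, p_occlusion = p_occlusion)
}

rotate_image <- function(img, theta) {
  if (theta == 0) return(img)
  d <- dim(img)
  cy <- (d[1] + 1) / 2
  cx <- (d[2] + 1) / 2
  gx <- matrix(rep(seq_len(d[2]), each = d[1]), d[1])
  gy <- matrix(rep(seq_len(d[1]), d[2]), d[1])
  xs <- cos(theta) * (gx - cx) + sin(theta) * (gy - cy) + cx
  ys <- -sin(theta) * (gx - cx) + cos(theta) * (gy - cy) + cy
  x0 <- pmin(pmax(floor(xs), 1), d[2] - 1)
  y0 <- pmin(pmax(floor(ys), 1), d[1] - 1)
  fx <- pmin(pmax(xs - x0, 0), 1)
  fy <- pmin(pmax(ys - y0, 0), 1)
  outside <- xs < 1 | xs > d[2] | ys < 1 | ys > d[1]
  iy0 <- as.vector(y0); ix0 <- as.vector(x0)
  wfy <- as.vector(fy); wfx <- as.vector(fx)
  out <- img
  for (ch in seq_len(d[3])) {
    sl <- img[, , ch]
    v <- sl[cbind(iy0, ix0)] * (1 - wfy) * (1 - wfx) +
      sl[cbind(iy0, ix0 + 1)] * (1 - wfy) * wfx +
      sl[cbind(iy0 + 1, ix0)] * wfy * (1 - wfx) +
      sl[cbind(iy0 + 1, ix0 + 1)] * wfy * wfx
    v[as.vector(outside)] <- mean(sl)
    out[, , ch] <- matrix(v, d[1], d[2])
  }
  out
}

#' Apply seeded training-time augmentation to a sample
#'
#' Optional horizontal/vertical flips, rotation within the configured
#' range, additive Gaussian noise, and a randomly placed occluding square.
#' The label is preserved and the drawn parameters are recorded in the
#' sample's provenance.
#'
#' @param s A `cow_sample` (or any list with an `image` array).
#' @param cfg An [augment_config()] list.
#' @param seed Integer seed for the augmentation draws.
#' @return The augmented sample.
#' @export
augment <- function(s, cfg = augment_config(), seed = 1L) {
  img <- s$image
  d <- dim(img)
  if (max(cfg$occlusion_size) > min(d[1], d[2])) {
    stop("occluder larger than the image", call. = FALSE)
  }
  old_rng <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng,
                                        envir = globalenv()))
  set.seed(seed)
  draws <- list()
  if (stats::runif(1) < cfg$p_hflip) {
    img <- img[, d[2]:1, , drop = FALSE]
    draws$hflip <- TRUE
  }
  if (stats::runif(1) < cfg$p_vflip) {
    img <- img[d[1]:1, , , drop = FALSE]
    draws$vflip <- TRUE
  }
  if (cfg$rotation_range > 0) {
    ang <- stats::runif(1, -cfg$rotation_range, cfg$rotation_range)
    img <- rotate_image(img, ang * pi / 180)
    draws$rotation <- ang
  }
  if (cfg$noise_sd > 0) {
    img <- pmin(pmax(img + stats::rnorm(length(img), 0, cfg$noise_sd), 0), 1)
    draws$noise_sd <- cfg$noise_sd
  }
  if (cfg$p_occlusion > 0 && stats::runif(1) < cfg$p_occlusion) {
    k <- if (cfg$occlusion_size[1] == cfg$occlusion_size[2])
      cfg$occlusion_size[1]
    else sample(cfg$occlusion_size[1]:cfg$occlusion_size[2], 1)
    oy <- sample(d[1] - k + 1, 1)
    ox <- sample(d[2] - k + 1, 1)
    img[oy:(oy + k - 1), ox:(ox + k - 1), ] <- cfg$occlusion_fill
    draws$occlusion <- c(y = oy, x = ox, k = k)
  }
  s$image <- img
  s$provenance$augment <- draws
  s
}

to_gray <- function(img) {
  if (length(dim(img)) == 3L) {
    0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  } else {
    img
  }
}

conv2_valid <- function(img, kern) {
  d <- dim(img)
  k <- nrow(kern)
  x <- img
  dim(x) <- c(1L, d[1], d[2], 1L)
  cols <- cb_im2col(x, 1L, d[1], d[2], 1L, k, 1L, 0L)
  matrix(crossprod(as.vector(kern), cols), d[1] - k + 1L, d[2] - k + 1L)
}

#' Structural similarity index (SSIM) between two images
#'
#' Windowed SSIM with the canonical constants (`K1 = 0.01`, `K2 = 0.03`,
#' dynamic range 1) and an 11x11 Gaussian window (sigma 1.5), evaluated on
#' fully interior windows and averaged.  Color images are converted to
#' luminance first.
#'
#' @param a,b Numeric images of identical shape, values in `[0, 1]`;
#'   either grayscale matrices or `(H, W, 3)` arrays.
#' @param window Window side length (odd; reduced for small images).
#' @param sigma Gaussian window standard deviation.
#' @return SSIM value in `[-1, 1]`.
#' @export
ssim <- function(a, b, window = 11L, sigma = 1.5) {
  if (!identical(dim(a), dim(b))) stop("images differ in shape", call. = FALSE)
  ga <- to_gray(a)
  gb <- to_gray(b)
  k <- min(window, dim(ga))
  if (k %% 2 == 0) k <- k - 1L
  g1 <- exp(-((seq_len(k) - (k + 1) / 2)^2) / (2 * sigma^2))
  kern <- outer(g1, g1)
  kern <- kern / sum(kern)
  mu_a <- conv2_valid(ga, kern)
  mu_b <- conv2_valid(gb, kern)
  va <- conv2_valid(ga * ga, kern) - mu_a^2
  vb <- conv2_valid(gb * gb, kern) - mu_b^2
  vab <- conv2_valid(ga * gb, kern) - mu_a * mu_b
  c1 <- 0.01^2
  c2 <- 0.03^2
  smap <- ((2 * mu_a * mu_b + c1) * (2 * vab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  mean(smap)
}

#' Keep every k-th frame of an ordered sequence
#'
#' @param frames List of images or samples, in order.
#' @param k Step (default 10: keep frames 1, 11, 21, ...).
#' @return The subsampled list.
#' @export
subsample_frames <- function(frames, k = 10L) {
  if (length(frames) == 0) return(frames)
  frames[seq(1, length(frames), by = k)]
}

sample_image <- function(fr) if (is.list(fr) && !is.null(fr$image)) fr$image else fr

#' Greedy SSIM deduplication of an ordered frame sequence
#'
#' Keeps the first frame, then keeps each subsequent frame only if its SSIM
#' to the most recently kept frame is below the threshold, so runs of
#' near-identical frames collapse to one.
#'
#' @param frames List of images (or `cow_sample`s), in sequence order.
#' @param threshold Similarity threshold in (0, 1); default 0.78.
#' @return The kept sublist, with the kept indices in attribute `"indices"`.
#' @export
dedup_frames <- function(frames, threshold = 0.78) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  if (length(frames) == 0) return(frames)
  kept <- 1L
  last <- sample_image(frames[[1]])
  for (i in seq_along(frames)[-1]) {
    cur <- sample_image(frames[[i]])
    if (ssim(cur, last) < threshold) {
      kept <- c(kept, i)
      last <- cur
    }
  }
  structure(frames[kept], indices = kept)
}

#' Herd configuration for the synthetic dataset generator
#'
#' @param n_identities Number of identities (default 10).
#' @param images_per_identity Retained images targeted per identity after
#'   deduplication (default 64; must be at least 40 for the minimum-count
#'   rule to keep every identity).
#' @param view_probs Named numeric vector of view probabilities.
#' @param view_persistence Probability that consecutive frames keep the
#'   same view (default 0.5).
#' @param augmentation An [augment_config()] list (used at training time).
#' @param ssim_threshold Deduplication threshold (default 0.78).
#' @param split Train/val/test ratio triple (default `c(7, 2, 1)`,
#'   normalized internally).
#' @param min_images Identities with fewer retained images are dropped
#'   (default 40).
#' @param image_size Rendered image side in pixels (default 48).
#' @param patch_scale,white_fraction_range Coat-pattern parameters; patches
#'   default to 18 pattern pixels (of a 96-pixel grid) — Holstein dorsal
#'   blotches are large relative to the back — and the white fraction is
#'   drawn per identity from the range.
#' @param p_duplicate Probability of appending a near-duplicate after each
#'   rendered frame, emulating consecutive video frames (default 0.3).
#' @param master_seed Integer master seed; the whole dataset is a pure
#'   function of the configuration including this seed.
#' @return A `herd_config` list.
#' @export
herd_config <- function(n_identities = 10L, images_per_identity = 64L,
                        view_probs = c(top = 0.4, `oblique-left` = 0.2,
                                       `oblique-right` = 0.2, rear = 0.2),
                        view_persistence = 0.5,
                        augmentation = augment_config(),
                        ssim_threshold = 0.78,
                        split = c(7, 2, 1), min_images = 40L,
                        image_size = 48L, patch_scale = 18,
                        white_fraction_range = c(0.25, 0.6),
                        p_duplicate = 0.3, master_seed = 1234L) {
  stopifnot(all(split > 0), length(split) == 3)
  if (ssim_threshold <= 0 || ssim_threshold >= 1) {
    stop("ssim_threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(list(n_identities = as.integer(n_identities),
                 images_per_identity = as.integer(images_per_identity),
                 view_probs = view_probs / sum(view_probs),
                 view_persistence = view_persistence,
                 augmentation = augmentation,
                 ssim_threshold = ssim_threshold,
                 split = split / sum(split),
                 min_images = as.integer(min_images),
                 image_size = as.integer(image_size),
                 patch_scale = patch_scale,
                 white_fraction_range = white_fraction_range,
                 p_duplicate = p_duplicate,
                 master_seed = as.integer(master_seed)),
            class = "herd_config")
}

#' Drop identities with too few retained images
#'
#' @param frame_lists List (one element per identity) of frame lists.
#' @param min_images Minimum retained-frame count (default 40).
#' @return The sublist of identities meeting the minimum.
#' @export
filter_identities <- function(frame_lists, min_images = 40L) {
  frame_lists[lengths(frame_lists) >= min_images]
}

# stratified per-identity split: floor for val and test, remainder to train
split_counts <- function(n, ratios) {
  nv <- as.integer(floor(n * ratios[2]))
  nt <- as.integer(floor(n * ratios[3]))
  c(train = as.integer(n) - nv - nt, val = nv, test = nt)
}

#' Generate, deduplicate, filter, and split a synthetic herd dataset
#'
#' For each identity, frames are synthesized (with occasional near-duplicate
#' successors, emulating consecutive video frames) until the target number
#' survives SSIM deduplication; identities with fewer than `min_images`
#' retained frames are dropped; the rest are split per identity at the
#' configured ratios (floor for val/test, remainder to train).  The result
#' is a pure function of the configuration.
#'
#' @param cfg A [herd_config()].
#' @param dir Optional directory; when given, an image-folder tree
#'   `dir/<split>/<identity>/*.png` plus `manifest.csv` is written.
#' @return A `herd_dataset` list: `train`, `val`, `test` (lists of
#'   `cow_sample`s with integer `label_idx`), `identities`, and a
#'   `manifest` data frame.
#' @export
build_dataset <- function(cfg = herd_config(), dir = NULL) {
  old_rng <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng,
                                        envir = globalenv()))
  set.seed(cfg$master_seed)
  views <- names(cfg$view_probs)
  id_seeds <- sample.int(2^30, cfg$n_identities)
  per_id <- list()
  for (i in seq_len(cfg$n_identities)) {
    wf <- stats::runif(1, cfg$white_fraction_range[1],
                       cfg$white_fraction_range[2])
    pat <- generate_pattern(id_seeds[i], cfg$patch_scale, wf,
                            id = sprintf("cow%02d", i))
    frames <- list()
    kept <- list()
    rounds <- 0L
    view <- sample(views, 1, prob = cfg$view_probs)
    while (length(kept) < cfg$images_per_identity && rounds < 6L) {
      rounds <- rounds + 1L
      need <- cfg$images_per_identity - length(kept)
      for (f in seq_len(need)) {
        if (stats::runif(1) > cfg$view_persistence) {
          view <- sample(views, 1, prob = cfg$view_probs)
        }
        s <- render_view(pat, view, stats::runif(1, 0.8, 1.15),
                         seed = sample.int(2^30, 1), size = cfg$image_size)
        frames[[length(frames) + 1L]] <- s
        if (stats::runif(1) < cfg$p_duplicate) {
          dup <- s
          dup$image <- pmin(pmax(
            dup$image + stats::rnorm(length(dup$image), 0, 0.004), 0), 1)
          dup$provenance$near_duplicate <- TRUE
          frames[[length(frames) + 1L]] <- dup
        }
      }
      kept <- dedup_frames(frames, cfg$ssim_threshold)
    }
    per_id[[i]] <- kept
  }
  per_id <- filter_identities(per_id, cfg$min_images)
  if (length(per_id) == 0) {
    stop("all identities fell below the minimum image count (",
         cfg$min_images, ")", call. = FALSE)
  }
  ids <- vapply(per_id, function(fr) fr[[1]]$label, "")
  out <- list(train = list(), val = list(), test = list())
  manifest <- NULL
  for (i in seq_along(per_id)) {
    fr <- per_id[[i]]
    n <- length(fr)
    cnt <- split_counts(n, cfg$split)
    perm <- sample(n)
    assign_split <- rep(c("val", "test", "train"),
                        c(cnt["val"], cnt["test"], cnt["train"]))
    for (j in seq_len(n)) {
      s <- fr[[perm[j]]]
      s$label_idx <- i
      sp <- assign_split[j]
      out[[sp]][[length(out[[sp]]) + 1L]] <- s
      manifest <- rbind(manifest, data.frame(
        identity = ids[i], split = sp, view = s$view,
        seed = s$provenance$seed,
        lighting_gain = round(s$provenance$lighting_gain, 6)))
    }
  }
  ds <- structure(list(train = out$train, val = out$val, test = out$test,
                       identities = ids, manifest = manifest, config = cfg),
                  class = "herd_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' Write a herd dataset as an image-folder tree with a manifest
#'
#' @param ds A `herd_dataset`.
#' @param dir Output root; creates `dir/<split>/<identity>/img_xxxx.png`
#'   and `dir/manifest.csv`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  counter <- 0L
  paths <- character(nrow(ds$manifest))
  row <- 0L
  for (sp in c("train", "val", "test")) {
    for (s in ds[[sp]]) {
      d <- file.path(dir, sp, s$label)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      counter <- counter + 1L
      png::writePNG(aperm(s$image, c(1, 2, 3)),
                    file.path(d, sprintf("img_%05d.png", counter)))
    }
  }
  utils::write.csv(ds$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read an image-folder tree back into sample lists
#'
#' @param dir Dataset root written by [write_dataset()] (or any
#'   `split/identity/*.png` tree).
#' @return A `herd_dataset`-like list with `train`/`val`/`test` samples.
#' @export
read_dataset <- function(dir) {
  out <- list(train = list(), val = list(), test = list())
  ids <- character(0)
  for (sp in c("train", "val", "test")) {
    spd <- file.path(dir, sp)
    if (!dir.exists(spd)) next
    for (idd in list.dirs(spd, recursive = FALSE)) {
      id <- basename(idd)
      if (!id %in% ids) ids <- c(ids, id)
      for (f in list.files(idd, pattern = "\\.png$", full.names = TRUE)) {
        img <- png::readPNG(f)
        if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
        out[[sp]][[length(out[[sp]]) + 1L]] <-
          structure(list(image = img[, , 1:3], label = id,
                         label_idx = match(id, ids), view = NA_character_,
                         provenance = list(path = f)),
                    class = "cow_sample")
      }
    }
  }
  structure(c(out, list(identities = ids, manifest = NULL, config = NULL)),
            class = "herd_dataset")
}
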