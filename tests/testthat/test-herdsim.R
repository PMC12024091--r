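test_that("coat patterns are reproducible, calibrated, and distinct across seeds", {
  p1 <- generate_pattern(101, 10, 0.5)
  p2 <- generate_pattern(101, 10, 0.5)
  expect_identical(p1$pattern, p2$pattern)
  expect_true(all(p1$pattern %in% c(0, 1)))
  # quantile thresholding pins the white share
  expect_equal(mean(p1$pattern), 0.5, tolerance = 0.02)
  expect_equal(mean(generate_pattern(55, 8, 0.3)$pattern), 0.3,
               tolerance = 0.02)
  # collision check over 100 seed pairs
  hams <- vapply(1:100, function(i) {
    a <- generate_pattern(2 * i, 10, 0.4)$pattern
    b <- generate_pattern(2 * i + 1, 10, 0.4)$pattern
    mean(a != b)
  }, 1)
  expect_true(all(hams > 0.01))
  expect_error(generate_pattern(1, 10, 0.96), "white_fraction")
  expect_error(generate_pattern(1, -1, 0.5), "patch_scale")
})

test_that("rendered views are seeded, bounded, and respond to lighting and viewpoint", {
  p <- generate_pattern(7, 10, 0.4)
  s1 <- render_view(p, "top", 1, seed = 3)
  s2 <- render_view(p, "top", 1, seed = 3)
  expect_identical(s1$image, s2$image)
  expect_true(all(s1$image >= 0 & s1$image <= 1))
  # unjittered top view shows the pattern's two tones exactly on the body
  s <- render_view(p, "top", 1, seed = 3, jitter = FALSE)
  body_vals <- unique(round(s$image[, , 1][abs(s$image[, , 1] -
    s$image[, , 2]) < 1e-12 & s$image[, , 1] %in% c(0.10, 0.88)], 2))
  expect_true(all(c(0.10, 0.88) %in% body_vals))
  # zero lighting gain blacks out the frame
  expect_true(all(render_view(p, "top", 0, seed = 3)$image == 0))
  # oblique perspectives shrink the visible body area
  top <- render_view(p, "top", 1, seed = 3, jitter = FALSE)
  for (v in c("oblique-left", "oblique-right", "rear")) {
    expect_lt(render_view(p, v, 1, seed = 3, jitter = FALSE)$body_frac,
              top$body_frac)
  }
})

test_that("augmentation draws are seeded and behave as documented", {
  p <- generate_pattern(9, 10, 0.4)
  s <- render_view(p, "top", 1, seed = 5)
  # all probabilities zero, no noise: the identity augmentation
  id_cfg <- augment_config(p_hflip = 0, p_vflip = 0, rotation_range = 0,
                           noise_sd = 0, p_occlusion = 0)
  expect_identical(augment(s, id_cfg, seed = 1)$image, s$image)
  # horizontal flip is an involution
  flip_cfg <- augment_config(p_hflip = 1, p_vflip = 0, rotation_range = 0,
                             noise_sd = 0, p_occlusion = 0)
  expect_identical(augment(augment(s, flip_cfg, 1), flip_cfg, 2)$image,
                   s$image)
  # a k x k occluder replaces exactly k^2 pixels
  occ_cfg <- augment_config(p_hflip = 0, p_vflip = 0, rotation_range = 0,
                            noise_sd = 0, p_occlusion = 1,
                            occlusion_size = c(6L, 6L))
  a <- augment(s, occ_cfg, seed = 2)
  changed <- apply(a$image != s$image, c(1, 2), any)
  expect_identical(sum(changed), 36L)
  expect_identical(a$provenance$augment$occlusion[["k"]], 6L)
  expect_identical(a$label, s$label)
  big <- augment_config(occlusion_size = c(80L, 90L))
  expect_error(augment(s, big, 1), "larger than the image")
})

test_that("SSIM has its defining fixed points and matches a windowed oracle", {
  set.seed(51)
  x <- matrix(runif(24 * 24), 24)
  expect_equal(ssim(x, x), 1)
  # independent noise images are structurally dissimilar
  vals <- vapply(1:5, function(i) {
    set.seed(100 + i)
    ssim(matrix(runif(32 * 32), 32), matrix(runif(32 * 32), 32))
  }, 1)
  expect_true(all(abs(vals) < 0.1))
  # small brightness change perturbs SSIM less than scrambling the pixels
  set.seed(52)
  bright <- pmin(x + 0.05, 1)
  scram <- matrix(sample(x), 24)
  expect_gt(ssim(x, bright), ssim(x, scram))
  # windowed-statistics oracle (explicit loops) on a small image
  set.seed(53)
  a <- matrix(runif(12 * 12), 12)
  b <- pmin(pmax(a + rnorm(144, 0, 0.1), 0), 1)
  expect_equal(ssim(a, b, window = 5, sigma = 1.5),
               oracle_ssim_gray(a, b, 5, 1.5), tolerance = 1e-10)
  expect_error(ssim(a, matrix(0, 5, 5)), "shape")
})

test_that("frame subsampling and greedy deduplication follow the stated rules", {
  set.seed(54)
  base <- matrix(runif(32 * 32), 32)
  expect_length(subsample_frames(as.list(1:25), 10), 3)
  # identical frames collapse to one
  same <- replicate(6, base, simplify = FALSE)
  expect_length(dedup_frames(same, 0.78), 1)
  # mutually dissimilar noise frames all survive
  noise <- lapply(1:5, function(i) { set.seed(200 + i); matrix(runif(1024), 32) })
  expect_length(dedup_frames(noise, 0.78), 5)
  expect_identical(attr(dedup_frames(noise, 0.78), "indices"), 1:5)
  # a threshold near 1 keeps all clearly distinct frames
  set.seed(55)
  near <- lapply(1:4, function(i) pmin(pmax(base + rnorm(1024, 0, 0.08),
                                            0), 1))
  expect_length(dedup_frames(near, 0.999), 4)
  # raising the threshold never decreases the number kept
  seqs <- c(same[1:3], near, noise)
  kept <- vapply(c(0.2, 0.5, 0.78, 0.95, 0.999),
                 function(th) length(dedup_frames(seqs, th)), 1)
  expect_true(all(diff(kept) >= 0))
  expect_length(dedup_frames(list(), 0.78), 0)
  expect_error(dedup_frames(same, 1.2), "threshold")
})

test_that("identity filtering and split arithmetic follow the stated rounding rule", {
  # 40 retained images split 28 / 8 / 4 at ratios 7:2:1
  expect_identical(cowbacknet:::split_counts(40, c(0.7, 0.2, 0.1)),
                   c(train = 28L, val = 8L, test = 4L))
  expect_identical(cowbacknet:::split_counts(45, c(0.7, 0.2, 0.1)),
                   c(train = 32L, val = 9L, test = 4L))
  # identities below the minimum are excluded
  lists <- list(as.list(1:40), as.list(1:39), as.list(1:41))
  kept <- filter_identities(lists, 40)
  expect_length(kept, 2)
  expect_identical(lengths(kept), c(40L, 41L))
})

test_that("a small herd build is stratified and reproducible end to end", {
  cfg <- herd_config(n_identities = 2, images_per_identity = 12,
                     min_images = 10, image_size = 32, master_seed = 77)
  ds <- build_dataset(cfg)
  expect_setequal(unique(ds$manifest$split), c("train", "val", "test"))
  # every identity appears in every split
  tab <- table(ds$manifest$identity, ds$manifest$split)
  expect_true(all(tab > 0))
  # per-identity counts follow the floor/floor/remainder rule
  for (id in rownames(tab)) {
    n <- sum(tab[id, ])
    expect_identical(unname(tab[id, c("train", "val", "test")]),
                     unname(cowbacknet:::split_counts(n, cfg$split)))
  }
  ds2 <- build_dataset(cfg)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$train[[1]]$image, ds2$train[[1]]$image)
  # samples carry values in [0,1] and labels from the herd
  expect_true(all(vapply(ds$train, function(s)
    all(s$image >= 0 & s$image <= 1), TRUE)))
  expect_true(all(vapply(ds$train, function(s) s$label, "") %in%
                    ds$identities))
})
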