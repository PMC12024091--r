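test_that("ECA channel attention matches the scalar brute-force oracle", {
  set.seed(1)
  for (case in list(c(4, 3, 3), c(8, 8, 8), c(1, 2, 5), c(6, 1, 1))) {
    f <- rand_fmap(case[1], case[2], case[3])
    for (k in c(1L, 3L, 5L)) {
      w <- rnorm(k)
      got <- eca_channel_attention(f, k, w)
      want <- oracle_eca(f, k, w)
      expect_equal(got, want, tolerance = 1e-5)
      expect_true(all(got > 0 & got < 1))
      expect_length(got, case[1])
    }
  }
})

test_that("ECA degenerate cases: zero weights gate at 0.5, k=1 is pointwise", {
  f <- array(0.7, c(4, 3, 3))
  expect_equal(eca_channel_attention(f, 3, c(0, 0, 0)), rep(0.5, 4))
  # permutation equivariance when the conv is pointwise
  f <- rand_fmap(6, 4, 4, seed = 2)
  perm <- c(3, 1, 6, 2, 5, 4)
  w <- 0.8
  expect_equal(eca_channel_attention(f[perm, , ], 1, w),
               eca_channel_attention(f, 1, w)[perm])
  expect_error(eca_channel_attention(f, 2), "odd")
  expect_error(eca_channel_attention(array(Inf, c(1, 1, 1)), 1), "finite")
})

test_that("CBAM spatial attention matches the scalar convolution oracle", {
  set.seed(3)
  # 1-channel map: mean and max pools coincide
  f1 <- rand_fmap(1, 3, 3)
  w3 <- array(rnorm(18), c(3, 3, 2))
  expect_equal(cbam_spatial_attention(f1, 3, w3),
               oracle_spatial(f1, 3, w3), tolerance = 1e-5)
  for (case in list(c(4, 5, 6), c(8, 8, 8), c(2, 7, 3))) {
    f <- rand_fmap(case[1], case[2], case[3])
    for (k in c(3L, 7L)) {
      w <- array(rnorm(k * k * 2), c(k, k, 2))
      b <- rnorm(1)
      got <- cbam_spatial_attention(f, k, w, b)
      expect_equal(got, oracle_spatial(f, k, w, b), tolerance = 1e-5)
      expect_identical(dim(got), dim(f)[2:3])
      expect_true(all(got > 0 & got < 1))
    }
  }
  expect_equal(cbam_spatial_attention(array(0.3, c(5, 4, 4)), 7,
                                      array(0, c(7, 7, 2))),
               matrix(0.5, 4, 4))
  expect_error(cbam_spatial_attention(f1, 4), "odd")
})

test_that("channel/spatial application match the triple-loop oracle", {
  set.seed(4)
  f <- rand_fmap(5, 4, 3)
  w <- runif(5)
  s <- matrix(runif(12), 4, 3)
  expect_identical(apply_channel(f, rep(1, 5)), f)
  expect_true(all(apply_channel(f, rep(0, 5)) == 0))
  expect_equal(apply_channel(f, w), oracle_mul_channel(f, w))
  expect_identical(apply_spatial(f, matrix(1, 4, 3)), f)
  expect_equal(apply_spatial(f, s), oracle_mul_spatial(f, s))
  ind <- matrix(0, 4, 3); ind[2, 3] <- 1
  out <- apply_spatial(f, ind)
  expect_equal(out[, 2, 3], f[, 2, 3])
  out[, 2, 3] <- 0
  expect_true(all(out == 0))
  expect_error(apply_channel(f, rep(1, 4)), "channel count")
  expect_error(apply_spatial(f, matrix(1, 3, 4)), "shape")
})

test_that("tandem fusion composes channel then spatial attention", {
  set.seed(5)
  f <- rand_fmap(6, 5, 5)
  p <- fusion_params(eca_weights = rnorm(3),
                     spatial_weights = array(rnorm(98), c(7, 7, 2)))
  got <- fuse_tandem(f, p)
  fc <- apply_channel(f, eca_channel_attention(f, 3, p$eca_weights))
  s <- cbam_spatial_attention(fc, 7, p$spatial_weights, p$spatial_bias)
  expect_identical(got, apply_spatial(fc, s))
  expect_identical(dim(got), dim(f))
  # all-zero conv weights: two successive 0.5 gates
  p0 <- fusion_params(eca_weights = rep(0, 3),
                      spatial_weights = array(0, c(7, 7, 2)))
  expect_equal(fuse_tandem(f, p0), 0.25 * f)
})

test_that("weighted fusion interpolates and hits its endpoints bit-exactly", {
  set.seed(6)
  f <- rand_fmap(4, 6, 3)
  mk <- function(alpha_raw) {
    fusion_params(alpha_raw, eca_weights = rnorm(3),
                  spatial_weights = array(rnorm(98), c(7, 7, 2)),
                  spatial_bias = 0.2)
  }
  set.seed(7); p1 <- mk(Inf)
  set.seed(7); p0 <- mk(-Inf)
  set.seed(7); ph <- mk(0)
  fc <- apply_channel(f, eca_channel_attention(f, 3, p1$eca_weights))
  fs <- apply_spatial(fc, cbam_spatial_attention(fc, 7, p1$spatial_weights,
                                                 p1$spatial_bias))
  expect_identical(fuse_weighted(f, p1), fc)     # alpha = 1
  expect_identical(fuse_weighted(f, p0), fs)     # alpha = 0
  expect_equal(fuse_weighted(f, ph), (fc + fs) / 2)
})

test_that("the residual fusion is the weighted fusion plus the identity", {
  set.seed(8)
  for (rep in 1:3) {
    f <- rand_fmap(sample(1:8, 1), sample(1:6, 1), sample(1:6, 1))
    p <- fusion_params(rnorm(1), eca_weights = rnorm(3),
                       spatial_weights = array(rnorm(98), c(7, 7, 2)))
    expect_identical(fuse_weighted_residual(f, p), fuse_weighted(f, p) + f)
  }
  # alpha = 1 with zero attention weights: 0.5-gated channel branch + identity
  f <- rand_fmap(3, 4, 4)
  pz <- fusion_params(Inf, eca_weights = rep(0, 3),
                      spatial_weights = array(0, c(7, 7, 2)))
  expect_equal(fuse_weighted_residual(f, pz), 1.5 * f)
})

test_that("attention weights stay in (0,1) and shapes are preserved over random shapes", {
  set.seed(9)
  for (rep in 1:10) {
    cc <- sample(1:64, 1); hh <- sample(1:32, 1); ww <- sample(1:32, 1)
    f <- rand_fmap(cc, hh, ww)
    p <- fusion_params(rnorm(1), eca_weights = rnorm(3),
                       spatial_weights = array(rnorm(18), c(3, 3, 2)),
                       spatial_kernel = 3)
    wch <- eca_channel_attention(f, 3, p$eca_weights)
    sp <- cbam_spatial_attention(f, 3, p$spatial_weights)
    expect_true(all(wch > 0 & wch < 1))
    expect_true(all(sp > 0 & sp < 1))
    expect_identical(dim(fuse_weighted_residual(f, p)), dim(f))
  }
})

test_that("the fusion mixing weight alpha is learnable (nonzero exact gradient)", {
  set.seed(10)
  blk <- nn_lightcbam(5, "residual", 3, 3, alpha_init = 0.3)
  x <- array(rnorm(5 * 4 * 4 * 2), c(5, 4, 4, 2))
  ctx <- nn_ctx(training = TRUE)
  y <- nn_forward(blk, x, ctx)
  wts <- array(rnorm(length(y)), dim(y))
  nn_backward(blk, wts, ctx)
  g <- blk$g_alpha_raw
  expect_true(is.finite(g) && abs(g) > 1e-8)
  # matches central finite differences on the raw parameter
  eps <- 1e-5
  loss_at <- function(a) {
    blk$alpha_raw <- a
    sum(nn_forward(blk, x, nn_ctx()) * wts)
  }
  num <- (loss_at(0.3 + eps) - loss_at(0.3 - eps)) / (2 * eps)
  expect_equal(g, num, tolerance = 1e-4)
})
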