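# The engine's hand-derived backward passes are validated against central
# finite differences, parameter by parameter, on small random tensors.

test_that("convolution, depthwise, batch-norm, pooling and linear gradients match finite differences", {
  set.seed(21)
  x <- array(rnorm(6 * 5 * 4 * 3), c(6, 5, 4, 3))
  expect_lt(fd_gradcheck(nn_conv2d(6, 4, 3, stride = 2, bias = TRUE), x), 1e-4)
  expect_lt(fd_gradcheck(nn_conv2d(6, 3, 1), x), 1e-4)
  expect_lt(fd_gradcheck(nn_dwconv2d(6, 3, stride = 2), x), 1e-4)
  expect_lt(fd_gradcheck(nn_batchnorm(6), x), 1e-4)
  expect_lt(fd_gradcheck(nn_swish(), x), 1e-4)
  expect_lt(fd_gradcheck(nn_gap(), x), 1e-4)
  expect_lt(fd_gradcheck(nn_linear(6, 4), matrix(rnorm(18), 6, 3)), 1e-4)
})

test_that("attention block gradients match finite differences", {
  set.seed(22)
  x <- array(rnorm(6 * 5 * 4 * 2), c(6, 5, 4, 2))
  expect_lt(fd_gradcheck(nn_se(6, 4), x), 1e-4)
  expect_lt(fd_gradcheck(nn_eca(6, 3), x), 1e-4)
  expect_lt(fd_gradcheck(nn_cbam(6, reduction = 2, spatial_k = 3), x), 1e-4)
  expect_lt(fd_gradcheck(nn_ca(6, reduction = 2), x), 1e-4)
  for (v in c("residual", "weighted", "tandem")) {
    expect_lt(fd_gradcheck(nn_lightcbam(6, v, 3, 3), x), 1e-4)
  }
})

test_that("composite residual blocks propagate exact gradients", {
  set.seed(23)
  x <- array(rnorm(4 * 6 * 6 * 2), c(4, 6, 6, 2))
  blk <- cowbacknet:::mbconv_block(4L, 16L, 4L, c(1L, 3L, 1L),
                                   c(1L, 1L, 1L), "lightcbam_residual",
                                   list())
  expect_lt(fd_gradcheck(blk, x, n_entries = 4), 1e-4)
  eb <- cowbacknet:::edge_block(4L, 16L, 4L, c(3L, 1L), c(1L, 1L))
  expect_lt(fd_gradcheck(eb, x, n_entries = 4), 1e-4)
})

test_that("batch norm switches between batch and running statistics", {
  set.seed(24)
  bn <- nn_batchnorm(3)
  x <- array(rnorm(3 * 4 * 4 * 5, mean = 2, sd = 3), c(3, 4, 4, 5))
  y_tr <- nn_forward(bn, x, nn_ctx(training = TRUE))
  # batch statistics: normalized output has ~zero mean, unit sd per channel
  expect_equal(rowMeans(matrix(y_tr, 3)), rep(0, 3), tolerance = 1e-8)
  y_ev <- nn_forward(bn, x, nn_ctx(training = FALSE))
  # eval uses running statistics, still warming up after one update
  expect_false(isTRUE(all.equal(y_tr, y_ev)))
})

test_that("convolution agrees with a direct scalar computation", {
  set.seed(25)
  x <- array(rnorm(2 * 4 * 4), c(2, 4, 4, 1))
  l <- nn_conv2d(2, 3, 3, stride = 1, pad = 1, bias = TRUE)
  y <- nn_forward(l, x, nn_ctx())
  # scalar reference at a few positions
  for (co in 1:3) for (oy in c(1, 3)) for (ox in c(2, 4)) {
    acc <- l$b[co]
    for (ci in 1:2) for (ky in 1:3) for (kx in 1:3) {
      sy <- oy + ky - 2; sx <- ox + kx - 2
      if (sy >= 1 && sy <= 4 && sx >= 1 && sx <= 4) {
        acc <- acc + l$W[ci, ky, kx, co] * x[ci, sy, sx, 1]
      }
    }
    expect_equal(y[co, oy, ox, 1], acc, tolerance = 1e-10)
  }
})
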