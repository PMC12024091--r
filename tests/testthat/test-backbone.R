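test_that("the default architecture table is reproduced stage by stage", {
  spec <- default_cowbacknet_spec()
  expect_length(spec$stages, 8)
  s4 <- spec$stages[[5]]  # stage index 4
  expect_identical(s4$channels, c(192L, 192L, 96L))
  expect_identical(s4$layers, 3L)
  s7 <- spec$stages[[8]]
  expect_identical(s7$kernel_sizes, 1L)
  expect_identical(s7$channels, 1280L)
  expect_identical(s7$resolution, c(7L, 7L))
  expect_identical(spec$stages[[1]]$channels, 32L)  # 3 -> 32 stem
  expect_identical(spec$embedding_dim, 1280L)
  expect_identical(vapply(spec$stages, function(s) s$layers, 1L),
                   c(1L, 1L, 2L, 2L, 3L, 5L, 8L, 1L))
  chain <- resolution_chain(spec)
  expect_identical(chain$output, c(112L, 112L, 56L, 28L, 14L, 14L, 7L, 7L))
  # halving happens exactly at the stride-2 stages
  expect_identical(chain$input %/% chain$output,
                   vapply(spec$stages, function(s)
                     as.integer(prod(s$strides)), 1L))
})

test_that("a reduced-width model honors the forward shape contracts", {
  spec <- small_cowbacknet_spec(num_classes = 7, input_size = c(32L, 32L))
  m <- build_model(spec, seed = 5)
  x <- array(runif(3 * 32 * 32 * 2), c(3, 32, 32, 2))
  emb <- forward_features(m, x)
  expect_identical(dim(emb), c(2L, m$embedding_dim))
  expect_true(all(is.finite(emb)))
  lg <- classify(m, x)
  expect_identical(dim(lg), c(2L, 7L))
  # softmax rows sum to one
  p <- exp(lg - apply(lg, 1, max))
  p <- p / rowSums(p)
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
  # identical inputs give identical embeddings in eval mode
  x2 <- x[, , , c(1, 1)]
  e2 <- forward_features(m, x2)
  expect_identical(e2[1, ], e2[2, ])
  # top-5 set always contains the top-1 prediction
  o <- order(-lg[1, ])
  expect_true(o[1] %in% o[1:5])
  expect_error(forward_features(m, array(0, c(3, 16, 16, 1))), "expects")
})

test_that("weight initialization is reproducible from the seed", {
  spec <- small_cowbacknet_spec(num_classes = 4, input_size = c(32L, 32L))
  m1 <- build_model(spec, seed = 11)
  m2 <- build_model(spec, seed = 11)
  m3 <- build_model(spec, seed = 12)
  x <- array(runif(3 * 32 * 32), c(3, 32, 32, 1))
  expect_identical(classify(m1, x), classify(m2, x))
  expect_false(isTRUE(all.equal(classify(m1, x), classify(m3, x))))
})

test_that("swapping the attention module changes activations but never shapes", {
  x <- array(runif(3 * 32 * 32), c(3, 32, 32, 1))
  shapes <- list()
  logits <- list()
  for (attn in c("lightcbam_residual", "none", "se", "eca")) {
    spec <- small_cowbacknet_spec(num_classes = 5, attention = attn,
                                  input_size = c(32L, 32L))
    m <- build_model(spec, seed = 3)
    ctx <- nn_ctx(trace = TRUE)
    lg <- nn_forward(m$net, cowbacknet:::normalize_input(m, x), ctx)
    shapes[[attn]] <- lapply(
      mget(c("features.stage4", "features.stage6"), envir = ctx$acts), dim)
    logits[[attn]] <- lg
  }
  expect_identical(shapes[["lightcbam_residual"]], shapes[["none"]])
  expect_identical(shapes[["se"]], shapes[["eca"]])
  expect_false(isTRUE(all.equal(logits[["lightcbam_residual"]],
                                logits[["none"]])))
})

test_that("gradients flow back to the early stages through the residual fusion", {
  spec <- small_cowbacknet_spec(num_classes = 3, input_size = c(32L, 32L))
  m <- build_model(spec, seed = 9)
  x <- array(runif(3 * 32 * 32 * 2), c(3, 32, 32, 2))
  ctx <- nn_ctx(training = TRUE, trace = TRUE)
  lg <- nn_forward(m$net, cowbacknet:::normalize_input(m, x), ctx)
  p <- exp(lg) / rep(colSums(exp(lg)), each = 3)
  gy <- p
  gy[1, ] <- gy[1, ] - 1
  nn_backward(m$net, gy, ctx)
  g2 <- get("features.stage2", envir = ctx$grads)
  expect_gt(sum(abs(g2)), 0)
})

test_that("perturbing a fusion mixing weight changes the embedding", {
  spec <- small_cowbacknet_spec(num_classes = 3, input_size = c(32L, 32L))
  m <- build_model(spec, seed = 13)
  x <- array(runif(3 * 32 * 32), c(3, 32, 32, 1))
  e0 <- forward_features(m, x)
  lcb <- Filter(function(l) inherits(l, "nn_lightcbam"),
                cowbacknet:::nn_leaves(m$features))
  expect_gt(length(lcb), 0)
  lcb[[1]]$alpha_raw <- lcb[[1]]$alpha_raw + 1
  e1 <- forward_features(m, x)
  expect_false(isTRUE(all.equal(e0, e1)))
})

test_that("baseline variants share the layer graph and only differ in attention", {
  s1 <- build_baseline("effv2", num_classes = 10, width_mult = 0.25,
                       input_size = c(32L, 32L))
  s2 <- build_baseline("effv2_eca", num_classes = 10, width_mult = 0.25,
                       input_size = c(32L, 32L))
  n1 <- model_layer_names(s1)
  n2 <- model_layer_names(s2)
  expect_identical(n1, n2)
  x <- array(runif(3 * 32 * 32), c(3, 32, 32, 1))
  expect_identical(dim(classify(s1, x)), dim(classify(s2, x)))
  # removing the SE bottleneck strictly reduces the parameter count
  expect_lt(count_params(s2), count_params(s1))
  expect_error(build_baseline("resnet"), "arg")
})
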