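toy_logits <- rbind(c(5, 1, 0, 0),   # correct
                    c(0, 4, 1, 0),   # correct
                    c(3, 2, 1, 0),   # correct
                    c(0, 1, 0, 5))   # wrong (true label 1)
toy_labels <- c(1L, 2L, 1L, 1L)

test_that("top-k accuracy matches enumeration on a toy table", {
  expect_equal(top_k_accuracy(toy_logits, toy_labels, 1), 0.75)
  # row 4 (true label 1, logits 0,1,0,5): top-2 = {4, 2}, still wrong;
  # at k = 3 the 0-valued tie between classes 1 and 3 breaks to class 1
  expect_equal(top_k_accuracy(toy_logits, toy_labels, 2), 0.75)
  expect_equal(top_k_accuracy(toy_logits, toy_labels, 3), 1)
  expect_equal(top_k_accuracy(toy_logits, toy_labels, 4), 1)  # k = C
  expect_equal(top_k_accuracy(diag(4), 1:4, 1), 1)            # all correct
  expect_error(top_k_accuracy(toy_logits, toy_labels, 5), "k must be")
})

test_that("top-k accuracy is monotone non-decreasing in k", {
  set.seed(41)
  for (rep in 1:10) {
    lg <- matrix(rnorm(20 * 8), 20, 8)
    lab <- sample(8, 20, replace = TRUE)
    accs <- vapply(1:8, function(k) top_k_accuracy(lg, lab, k), 1)
    expect_true(all(diff(accs) >= 0))
    expect_equal(accs[8], 1)
  }
})

test_that("per-class reports decompose the overall accuracy", {
  rep <- per_class_report(toy_logits, toy_labels)
  expect_identical(rep$N_total, 4L)
  expect_identical(rep$N_top1_correct, 3L)
  expect_equal(rep$top1, 0.75)
  expect_gte(rep$top5, rep$top1)
  expect_identical(sum(rep$per_class$n), rep$N_total)
  # overall top-1 equals the sample-weighted mean of per-class top-1
  expect_equal(sum(rep$per_class$n * rep$per_class$top1) / rep$N_total,
               rep$top1)
  # single class, all correct
  one <- per_class_report(matrix(c(3, 1, 2, 0), 2, 2), c(1L, 1L))
  expect_equal(one$per_class$top1, 1)
  # toy two-class table with one error in class B
  lg <- rbind(c(1, 0), c(1, 0), c(0, 1), c(1, 0.5))
  rp <- per_class_report(lg, c(1L, 1L, 2L, 2L))
  expect_equal(rp$per_class$top1, c(1, 0.5))
  expect_error(per_class_report(toy_logits[0, , drop = FALSE], integer(0)),
               "empty")
})

# A hand-built one-conv-one-linear network whose Grad-CAM has a closed form:
# logits_t = b_t + sum_c Wfc[c,t] * mean_yx(A[c,y,x]) so
# d logit_t / d A[c,y,x] = Wfc[c,t] / (H*W), the channel weights are
# Wfc[,t] / (H*W), and the map is ReLU(sum_c Wfc[c,t]/(H*W) * A[c,,]).
make_toy_model <- function(seed = 7, h = 8, w = 8) {
  set.seed(seed)
  m <- new.env()
  class(m) <- "cow_model"
  conv <- nn_conv2d(3, 4, 1, bias = TRUE)
  m$features <- cowbacknet:::nn_sequential(list(conv = conv,
                                                pool = cowbacknet:::nn_gap()))
  m$classifier <- nn_linear(4, 3)
  m$net <- cowbacknet:::nn_sequential(list(features = m$features,
                                           fc = m$classifier))
  m$spec <- list(input_size = c(h, w), norm_mean = 0, norm_sd = 1,
                 num_classes = 3L)
  m$embedding_dim <- 4L
  m
}

test_that("Grad-CAM on a closed-form toy network matches the analytic map", {
  m <- make_toy_model()
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  hm <- grad_cam(m, img, target_class = 2, layer = "features.conv")
  # analytic activations of the 1x1 conv
  conv <- m$features$children$conv
  x <- aperm(img, c(3, 1, 2))
  a <- array(0, c(4, 8, 8))
  for (co in 1:4) {
    a[co, , ] <- conv$b[co]
    for (ci in 1:3) a[co, , ] <- a[co, , ] + conv$W[ci, 1, 1, co] * x[ci, , ]
  }
  wfc <- m$classifier$W[, 2] / (8 * 8)
  cam <- matrix(0, 8, 8)
  for (co in 1:4) cam <- cam + wfc[co] * a[co, , ]
  cam[cam < 0] <- 0
  cam <- (cam - min(cam)) / (max(cam) - min(cam))
  expect_equal(hm$values, cam, tolerance = 1e-5)
  expect_false(hm$degenerate)
  expect_equal(max(hm$values), 1)
  expect_gte(min(hm$values), 0)
})

test_that("Grad-CAM is invariant to constant shifts of the logit biases", {
  m <- make_toy_model(seed = 8)
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  h1 <- grad_cam(m, img, 1, layer = "features.conv")
  m$classifier$b <- m$classifier$b + 5
  h2 <- grad_cam(m, img, 1, layer = "features.conv")
  expect_equal(h1$values, h2$values, tolerance = 1e-12)
})

test_that("Grad-CAM flags a degenerate all-zero map and rejects bad layers", {
  m <- make_toy_model(seed = 9)
  m$classifier$W[, 3] <- 0  # zero-weight head row: no evidence anywhere
  img <- array(runif(8 * 8 * 3), c(8, 8, 3))
  hm <- grad_cam(m, img, 3, layer = "features.conv")
  expect_true(hm$degenerate)
  expect_true(all(hm$values == 0))
  expect_error(grad_cam(m, img, 1, layer = "nope"), "valid layers")
})

test_that("bilinear upsampling preserves constants and corner values", {
  mat <- matrix(c(0, 1, 2, 3), 2, 2)
  up <- cowbacknet:::bilinear_upsample(mat, 5, 5)
  expect_equal(up[1, 1], 0)
  expect_equal(up[5, 5], 3)
  expect_equal(dim(up), c(5L, 5L))
  expect_equal(cowbacknet:::bilinear_upsample(matrix(2, 1, 1), 3, 4),
               matrix(2, 3, 4))
})
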