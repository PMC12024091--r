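# Recognition metrics and Grad-CAM interpretability.

#' Top-k classification accuracy
#'
#' Fraction of samples whose true label is among the `k` largest logits.
#' Ties are broken by the lower class index.
#'
#' @param logits Numeric matrix `n x C`.
#' @param labels Integer vector of true class indices in `1..C`.
#' @param k Number of top candidates considered.
#' @return Accuracy in `[0, 1]`.
#' @export
top_k_accuracy <- function(logits, labels, k = 1L) {
  logits <- as.matrix(logits)
  n <- nrow(logits)
  cc <- ncol(logits)
  if (k < 1 || k > cc) stop("k must be in 1..", cc, ", got ", k, call. = FALSE)
  stopifnot(length(labels) == n, n >= 1)
  hits <- vapply(seq_len(n), function(i) {
    labels[i] %in% order(-logits[i, ])[seq_len(k)]
  }, logical(1))
  mean(hits)
}

#' Overall and per-identity accuracy report
#'
#' Computes top-1 and top-5 accuracy over all samples plus per-identity
#' top-1 accuracy, the protocol used for per-cow accuracy profiles.
#'
#' @param logits Numeric matrix `n x C`.
#' @param labels Integer vector of true class indices in `1..C`.
#' @param class_names Optional character vector of identity names (length
#'   `C`).
#' @return List with `N_total`, `N_top1_correct`, `N_top5_correct`, `top1`,
#'   `top5`, and `per_class` (data frame with identity, n, top1).
#' @export
per_class_report <- function(logits, labels, class_names = NULL) {
  logits <- as.matrix(logits)
  n <- nrow(logits)
  if (n == 0) stop("empty logits", call. = FALSE)
  cc <- ncol(logits)
  if (is.null(class_names)) class_names <- as.character(seq_len(cc))
  k5 <- min(5L, cc)
  pred1 <- apply(logits, 1, which.max)
  top1_hit <- pred1 == labels
  top5_hit <- vapply(seq_len(n), function(i) {
    labels[i] %in% order(-logits[i, ])[seq_len(k5)]
  }, logical(1))
  cls <- sort(unique(labels))
  per <- data.frame(
    identity = class_names[cls],
    n = as.integer(tabulate(labels, cc)[cls]),
    top1 = vapply(cls, function(cl) mean(top1_hit[labels == cl]), 1))
  list(N_total = n,
       N_top1_correct = sum(top1_hit),
       N_top5_correct = sum(top5_hit),
       top1 = mean(top1_hit),
       top5 = mean(top5_hit),
       per_class = per)
}

# bilinear upsample with corner alignment
bilinear_upsample <- function(mat, h, w) {
  hi <- nrow(mat); wi <- ncol(mat)
  if (hi == 1 && wi == 1) return(matrix(mat[1, 1], h, w))
  ys <- if (hi == 1) rep(1, h) else seq(1, hi, length.out = h)
  xs <- if (wi == 1) rep(1, w) else seq(1, wi, length.out = w)
  y0 <- pmin(floor(ys), hi - 1L); x0 <- pmin(floor(xs), wi - 1L)
  if (hi == 1) y0 <- rep(1, h)
  if (wi == 1) x0 <- rep(1, w)
  fy <- ys - y0; fx <- xs - x0
  y1 <- pmin(y0 + 1, hi); x1 <- pmin(x0 + 1, wi)
  m00 <- mat[y0, x0, drop = FALSE]; m01 <- mat[y0, x1, drop = FALSE]
  m10 <- mat[y1, x0, drop = FALSE]; m11 <- mat[y1, x1, drop = FALSE]
  fyM <- matrix(fy, h, w); fxM <- matrix(fx, h, w, byrow = TRUE)
  m00 * (1 - fyM) * (1 - fxM) + m01 * (1 - fyM) * fxM +
    m10 * fyM * (1 - fxM) + m11 * fyM * fxM
}

#' Gradient-weighted class activation map (Grad-CAM)
#'
#' Backpropagates the target-class logit to a named convolutional sub-block,
#' weights the block's activations by the channel-averaged gradients,
#' rectifies, upsamples bilinearly to input resolution, and min-max
#' normalizes to `[0, 1]`.
#'
#' @param m A `cow_model`.
#' @param image Numeric array `(H, W, 3)` in `[0, 1]` (or `(3, H, W)`).
#' @param target_class Integer class index whose evidence is localized.
#' @param layer Dotted sub-block name (see [model_layer_names()]); defaults
#'   to the deepest inverted-residual block.
#' @return A `cow_heatmap` list: `values` (matrix at input resolution,
#'   max 1 unless degenerate), `target_class`, `layer`, `degenerate`.
#' @export
grad_cam <- function(m, image, target_class,
                     layer = "features.stage6.block8") {
  valid <- model_layer_names(m)
  if (!layer %in% valid) {
    stop("unknown layer '", layer, "'; valid layers are:\n  ",
         paste(valid, collapse = "\n  "), call. = FALSE)
  }
  x <- image_to_input(image)
  ctx <- nn_ctx(training = FALSE, grad = TRUE, trace = TRUE)
  logits <- nn_forward(m$net, normalize_input(m, x), ctx)
  stopifnot(target_class >= 1, target_class <= nrow(logits))
  gy <- matrix(0, nrow(logits), ncol(logits))
  gy[target_class, ] <- 1
  nn_backward(m$net, gy, ctx)
  a <- get(layer, envir = ctx$acts)
  g <- get(layer, envir = ctx$grads)
  da <- dim(a)
  wch <- rowMeans(matrix(g[, , , 1], da[1]))
  cam <- matrix(colSums(matrix(a[, , , 1], da[1]) * wch), da[2], da[3])
  cam[cam < 0] <- 0
  up <- bilinear_upsample(cam, dim(x)[2], dim(x)[3])
  mx <- max(up)
  degenerate <- mx <= 0
  if (!degenerate) up <- (up - min(up)) / (mx - min(up))
  structure(list(values = up, target_class = target_class, layer = layer,
                 degenerate = degenerate), class = "cow_heatmap")
}

# accept (H,W,3) or (3,H,W) single images, return (3,H,W,1)
image_to_input <- function(image) {
  d <- dim(image)
  if (length(d) == 3L && d[3] == 3L && d[1] != 3L) {
    image <- aperm(image, c(3, 1, 2))
    d <- dim(image)
  }
  if (length(d) != 3L || d[1] != 3L) {
    stop("image must be (H, W, 3) or (3, H, W)", call. = FALSE)
  }
  dim(image) <- c(d, 1L)
  image
}
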