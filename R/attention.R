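# Channel and spatial attention primitives and their fusion strategies.
#
# The functional API below operates on plain 3-D feature maps indexed
# (channel, row, col) and takes explicit weights, so every operation can be
# checked against scalar brute-force oracles.  The nn_* blocks further down
# are the trainable counterparts used inside the backbone.

check_odd <- function(k, what = "kernel size") {
  if (length(k) != 1L || !is.finite(k) || k < 1 || k %% 2 == 0) {
    stop(what, " must be a positive odd integer, got ", k, call. = FALSE)
  }
  as.integer(k)
}

check_fmap <- function(f) {
  if (!is.array(f) || length(dim(f)) != 3L || any(dim(f) < 1L)) {
    stop("feature map must be a 3-D array (channels, height, width)",
         call. = FALSE)
  }
  if (!all(is.finite(f))) stop("feature map contains non-finite values",
                               call. = FALSE)
  invisible(f)
}

# zero-padded 1-D convolution along the channel axis; g is (C, N)
conv1d_channels <- function(g, w) {
  k <- length(w)
  p <- (k - 1L) %/% 2L
  n <- ncol(g)
  gp <- rbind(matrix(0, p, n), g, matrix(0, p, n))
  cc <- nrow(g)
  z <- matrix(0, cc, n)
  for (j in seq_len(k)) z <- z + w[j] * gp[j:(j + cc - 1L), , drop = FALSE]
  list(z = z, gp = gp)
}

#' Efficient channel attention (ECA) weights
#'
#' Computes per-channel gating weights by global average pooling the feature
#' map and sliding a 1-D convolution of odd width `k` (zero padding, single
#' filter, no bias) across the channel descriptor, followed by a sigmoid.
#'
#' @param f 3-D numeric array `(channels, height, width)`.
#' @param k Odd kernel width of the channel convolution (default 3).
#' @param weights Numeric vector of length `k` with the convolution weights;
#'   defaults to an averaging kernel `rep(1/k, k)`.
#' @return Numeric vector of length `channels`, all entries in (0, 1).
#' @export
#' @examples
#' f <- array(seq_len(2 * 3 * 3) / 18, c(2, 3, 3))
#' eca_channel_attention(f, k = 3, weights = c(0.2, 0.5, 0.3))
eca_channel_attention <- function(f, k = 3L, weights = NULL) {
  check_fmap(f)
  k <- check_odd(k)
  if (is.null(weights)) weights <- rep(1 / k, k)
  stopifnot(length(weights) == k)
  g <- matrix(rowMeans(matrix(f, dim(f)[1])), ncol = 1)
  as.vector(sigmoid(conv1d_channels(g, weights)$z))
}

#' CBAM-style spatial attention map
#'
#' Pools the feature map channel-wise by mean and by maximum, stacks the two
#' maps, convolves them with a single `k x k` filter ("same" zero padding)
#' and applies a sigmoid, yielding one gating weight per pixel.
#'
#' @param f 3-D numeric array `(channels, height, width)`.
#' @param k Odd spatial kernel size (default 7).
#' @param weights Numeric array `(k, k, 2)`; `weights[,,1]` is applied to the
#'   mean-pooled map, `weights[,,2]` to the max-pooled map.  Defaults to a
#'   uniform filter `1/(2 k^2)`.
#' @param bias Scalar bias added before the sigmoid (default 0).
#' @return Matrix `(height, width)` with entries in (0, 1).
#' @export
cbam_spatial_attention <- function(f, k = 7L, weights = NULL, bias = 0) {
  check_fmap(f)
  k <- check_odd(k)
  if (is.null(weights)) weights <- array(1 / (2 * k * k), c(k, k, 2))
  stopifnot(all(dim(weights) == c(k, k, 2)))
  d <- dim(f)
  m <- matrix(f, d[1])
  avg <- colMeans(m)
  mx <- cb_colmax(m)$max
  stack <- array(0, c(2, d[2], d[3], 1))
  stack[1, , , 1] <- avg
  stack[2, , , 1] <- mx
  # reorder user weights (k, k, in) -> engine layout (in, k, k, out=1)
  wmat <- array(0, c(2, k, k, 1))
  wmat[1, , , 1] <- weights[, , 1]
  wmat[2, , , 1] <- weights[, , 2]
  cols <- cb_im2col(stack, 2L, d[2], d[3], 1L, k, 1L, (k - 1L) %/% 2L)
  z <- crossprod(matrix(wmat, nrow = 2 * k * k), cols) + bias
  matrix(sigmoid(z), d[2], d[3])
}

#' Apply per-channel attention weights
#'
#' @param f 3-D numeric array `(channels, height, width)`.
#' @param w Numeric vector of per-channel weights, length `channels`.
#' @return Array of the same shape as `f` with `out[c,y,x] = f[c,y,x] * w[c]`.
#' @export
apply_channel <- function(f, w) {
  check_fmap(f)
  if (length(w) != dim(f)[1]) {
    stop("length(w) = ", length(w), " does not match channel count ",
         dim(f)[1], call. = FALSE)
  }
  f * as.vector(w)  # channel is the fastest-varying dimension
}

#' Apply a spatial attention map
#'
#' @param f 3-D numeric array `(channels, height, width)`.
#' @param s Matrix `(height, width)` of per-pixel weights.
#' @return Array of the same shape as `f` with `out[c,y,x] = f[c,y,x] * s[y,x]`.
#' @export
apply_spatial <- function(f, s) {
  check_fmap(f)
  d <- dim(f)
  if (!all(dim(s) == d[2:3])) {
    stop("spatial map shape (", paste(dim(s), collapse = "x"),
         ") does not match feature map (", d[2], "x", d[3], ")",
         call. = FALSE)
  }
  f * rep(s, each = d[1])
}

#' Fusion parameters for composite attention
#'
#' Bundles the learnable mixing weight and the kernels/weights of the two
#' attention branches.  The mixing weight is stored unconstrained
#' (`alpha_raw`) and mapped through the logistic function so that
#' `alpha = sigmoid(alpha_raw)` always lies in `[0, 1]`; infinite raw values
#' reach the endpoints exactly.
#'
#' @param alpha_raw Unconstrained scalar; `alpha = sigmoid(alpha_raw)`.
#' @param eca_kernel Odd width of the channel-attention 1-D convolution.
#' @param spatial_kernel Odd size of the spatial-attention convolution.
#' @param eca_weights,spatial_weights,spatial_bias Optional explicit branch
#'   weights, as in [eca_channel_attention()] and [cbam_spatial_attention()].
#' @param spatial_from Whether the spatial branch sees the channel-adjusted
#'   map (`"channel"`, the default sequential reading) or the raw input
#'   (`"input"`).
#' @return An object of class `fusion_params`.
#' @export
fusion_params <- function(alpha_raw = 0, eca_kernel = 3L, spatial_kernel = 7L,
                          eca_weights = NULL, spatial_weights = NULL,
                          spatial_bias = 0,
                          spatial_from = c("channel", "input")) {
  check_odd(eca_kernel, "eca_kernel")
  check_odd(spatial_kernel, "spatial_kernel")
  structure(list(alpha_raw = alpha_raw, alpha = sigmoid(alpha_raw),
                 eca_kernel = as.integer(eca_kernel),
                 spatial_kernel = as.integer(spatial_kernel),
                 eca_weights = eca_weights,
                 spatial_weights = spatial_weights,
                 spatial_bias = spatial_bias,
                 spatial_from = match.arg(spatial_from)),
            class = "fusion_params")
}

fusion_branches <- function(f, p) {
  wc <- eca_channel_attention(f, p$eca_kernel, p$eca_weights)
  fc <- apply_channel(f, wc)
  base <- if (p$spatial_from == "channel") fc else f
  s <- cbam_spatial_attention(base, p$spatial_kernel, p$spatial_weights,
                              p$spatial_bias)
  list(fc = fc, fs = apply_spatial(fc, s))
}

#' Tandem (sequential) attention fusion
#'
#' Channel attention first, then spatial attention computed on and applied to
#' the channel-adjusted map.  The mixing weight in `p` is unused.
#'
#' @param f 3-D numeric array `(channels, height, width)`.
#' @param p A [fusion_params()] object.
#' @return Array of the same shape as `f`.
#' @export
fuse_tandem <- function(f, p) {
  fusion_branches(f, p)$fs
}

#' Weighted attention fusion
#'
#' Linear interpolation `alpha * Fc + (1 - alpha) * Fs` between the
#' channel-adjusted map `Fc` and the tandem result `Fs`.
#'
#' @inheritParams fuse_tandem
#' @return Array of the same shape as `f`.
#' @export
fuse_weighted <- function(f, p) {
  br <- fusion_branches(f, p)
  a <- p$alpha
  if (a == 1) return(br$fc)
  if (a == 0) return(br$fs)
  a * br$fc + (1 - a) * br$fs
}

#' Weighted attention fusion with residual shortcut (LightCBAM)
#'
#' The composite module: `alpha * Fc + (1 - alpha) * Fs + f`, i.e. the
#' weighted fusion plus an identity shortcut from the raw input.
#'
#' @inheritParams fuse_tandem
#' @return Array of the same shape as `f`.
#' @export
fuse_weighted_residual <- function(f, p) {
  fuse_weighted(f, p) + f
}

# ---------------------------------------------------------------------------
# Trainable attention blocks (engine layers).  Channel counts follow the
# inverted-residual convention: the block sees the expanded tensor but
# squeeze ratios refer to the hosting block's input channels.
# ---------------------------------------------------------------------------

swish_grad <- function(x, s) s * (1 + x * (1 - s))

# ---- squeeze-and-excitation -------------------------------------------------

#' Trainable attention blocks
#'
#' Engine blocks implementing squeeze-and-excitation, efficient channel
#' attention, CBAM (channel MLP + spatial gate), coordinate attention, and
#' the composite LightCBAM fusion module.  `ch` is the (expanded) channel
#' count the block sees; `ch_base` is the hosting block's input channel
#' count, which squeeze ratios refer to.
#'
#' @param ch,ch_base Channel counts (see above).
#' @param ratio,reduction Squeeze/bottleneck ratios.
#' @param k,eca_k 1-D channel-convolution width.
#' @param spatial_k Spatial-gate kernel size.
#' @param variant LightCBAM fusion variant: `"residual"`, `"weighted"`,
#'   or `"tandem"`.
#' @param alpha_init Initial raw mixing weight (`alpha = sigmoid(raw)`).
#' @param spatial_from Whether the spatial gate sees the channel-adjusted
#'   map (`"channel"`) or the raw input (`"input"`).
#' @return An engine layer (a mutable environment).
#' @name attention-blocks
NULL

#' @rdname attention-blocks
#' @export
nn_se <- function(ch, ch_base, ratio = 0.25) {
  rd <- max(1L, as.integer(round(ch_base * ratio)))
  b1 <- 1 / sqrt(ch)
  b2 <- 1 / sqrt(rd)
  l <- new_layer("se",
                 W1 = matrix(stats::runif(ch * rd, -b1, b1), ch, rd),
                 b1 = stats::runif(rd, -b1, b1),
                 W2 = matrix(stats::runif(rd * ch, -b2, b2), rd, ch),
                 b2 = stats::runif(ch, -b2, b2),
                 ch = ch, rd = rd)
  l$params <- c("W1", "b1", "W2", "b2")
  l
}

#' @export
nn_forward.nn_se <- function(layer, x, ctx = nn_ctx()) {
  g <- gap2d(x)
  h <- crossprod(layer$W1, g) + layer$b1
  hs <- sigmoid(h)
  a <- h * hs
  spre <- crossprod(layer$W2, a) + layer$b2
  s <- sigmoid(spre)
  if (ctx$grad) layer$cache <- list(x = x, g = g, h = h, hs = hs, a = a, s = s)
  bcast_cmul(x, s)
}

#' @export
nn_backward.nn_se <- function(layer, gy, ctx = nn_ctx(grad = TRUE)) {
  cc <- layer$cache
  layer$cache <- NULL
  d <- dims4(cc$x)
  gs <- cgate_sum(gy, cc$x)
  gx <- bcast_cmul(gy, cc$s)
  gspre <- gs * cc$s * (1 - cc$s)
  layer$g_W2 <- cc$a %*% t(gspre)
  layer$g_b2 <- rowSums(gspre)
  ga <- layer$W2 %*% gspre
  gh <- ga * swish_grad(cc$h, cc$hs)
  layer$g_W1 <- cc$g %*% t(gh)
  layer$g_b1 <- rowSums(gh)
  gg <- layer$W1 %*% gh
  gx + gap2d_expand(gg / (d[2] * d[3]), d[2], d[3])
}

# ---- efficient channel attention -------------------------------------------

#' @rdname attention-blocks
#' @export
nn_eca <- function(ch, k = 3L) {
  bound <- 1 / sqrt(k)
  l <- new_layer("eca", w = stats::runif(k, -bound, bound),
                 ch = ch, k = as.integer(k))
  l$params <- "w"
  l
}

#' @export
nn_forward.nn_eca <- function(layer, x, ctx = nn_ctx()) {
  g <- gap2d(x)
  cv <- conv1d_channels(g, layer$w)
  s <- sigmoid(cv$z)
  if (ctx$grad) layer$cache <- list(x = x, gp = cv$gp, s = s)
  bcast_cmul(x, s)
}

#' @export
nn_backward.nn_eca <- function(layer, gy, ctx = nn_ctx(grad = TRUE)) {
  cc <- layer$cache
  layer$cache <- NULL
  d <- dims4(cc$x)
  k <- layer$k
  chn <- d[1]
  gs <- cgate_sum(gy, cc$x)
  gz <- gs * cc$s * (1 - cc$s)
  gw <- numeric(k)
  for (j in seq_len(k)) {
    gw[j] <- sum(cc$gp[j:(j + chn - 1L), , drop = FALSE] * gz)
  }
  layer$g_w <- gw
  gg <- conv1d_channels(gz, rev(layer$w))$z
  bcast_cmul(gy, cc$s) + gap2d_expand(gg / (d[2] * d[3]), d[2], d[3])
}

# ---- shared spatial gate (mean/max stack -> k x k conv -> sigmoid) ---------

spat_gate_init <- function(k) nn_conv2d(2L, 1L, k, bias = TRUE)

spat_gate_forward <- function(blk, x, ctx) {
  d <- dims4(x)
  mm <- cb_meanmax(x, d[1], d[2], d[3], d[4])
  z <- nn_forward(blk$spconv, mm$stack, ctx)
  s <- array(sigmoid(z), c(d[2], d[3], d[4]))
  if (ctx$grad) blk$sp_cache <- list(idx = mm$idx, din = d, s = s)
  s
}

spat_gate_backward <- function(blk, gs) {
  cc <- blk$sp_cache
  blk$sp_cache <- NULL
  d <- cc$din
  gz <- gs * cc$s * (1 - cc$s)
  dim(gz) <- c(1, d[2], d[3], d[4])
  gstack <- nn_backward(blk$spconv, gz)
  cb_meanmax_bwd(gstack, cc$idx, d[1], d[2], d[3], d[4])
}

# ---- full CBAM (channel MLP on avg+max, then spatial gate) -----------------

#' @rdname attention-blocks
#' @export
nn_cbam <- function(ch, reduction = 16L, spatial_k = 7L) {
  rd <- max(1L, ch %/% reduction)
  b1 <- 1 / sqrt(ch)
  b2 <- 1 / sqrt(rd)
  l <- new_layer("cbam",
                 W1 = matrix(stats::runif(ch * rd, -b1, b1), ch, rd),
                 b1 = stats::runif(rd, -b1, b1),
                 W2 = matrix(stats::runif(rd * ch, -b2, b2), rd, ch),
                 b2 = stats::runif(ch, -b2, b2),
                 ch = ch, rd = rd)
  l$params <- c("W1", "b1", "W2", "b2")
  l$spconv <- spat_gate_init(spatial_k)
  l
}

#' @export
nn_forward.nn_cbam <- function(layer, x, ctx = nn_ctx()) {
  d <- dims4(x)
  gavg <- gap2d(x)
  # spatial max per (channel, sample)
  gmaxm <- matrix(0, d[1], d[4])
  idxm <- matrix(0L, d[1], d[4])
  for (n in seq_len(d[4])) {
    rm <- cb_rowmax(matrix(x[, , , n], d[1]))
    gmaxm[, n] <- rm$max
    idxm[, n] <- rm$idx
  }
  mlp <- function(v) {
    h <- crossprod(layer$W1, v) + layer$b1
    list(h = h, o = crossprod(layer$W2, h * (h > 0)) + layer$b2)
  }
  ma <- mlp(gavg)
  mm <- mlp(gmaxm)
  s <- sigmoid(ma$o + mm$o)
  x1 <- bcast_cmul(x, s)
  ss <- spat_gate_forward(layer, x1, ctx)
  if (ctx$grad) {
    layer$cache <- list(x = x, gavg = gavg, gmaxm = gmaxm, idxm = idxm,
                        ha = ma$h, hm = mm$h, s = s, x1 = x1, ss = ss)
  }
  bcast_smul(x1, ss)
}

#' @export
nn_backward.nn_cbam <- function(layer, gy, ctx = nn_ctx(grad = TRUE)) {
  cc <- layer$cache
  layer$cache <- NULL
  d <- dims4(cc$x)
  gss <- sgate_sum(gy, cc$x1)
  gx1 <- bcast_smul(gy, cc$ss)
  gx1 <- gx1 + spat_gate_backward(layer, gss)
  gs <- cgate_sum(gx1, cc$x)
  gx <- bcast_cmul(gx1, cc$s)
  go <- gs * cc$s * (1 - cc$s)
  # backward through the two shared-MLP branches
  layer$g_W1 <- matrix(0, nrow(layer$W1), ncol(layer$W1))
  layer$g_b1 <- numeric(layer$rd)
  layer$g_W2 <- matrix(0, nrow(layer$W2), ncol(layer$W2))
  layer$g_b2 <- numeric(layer$ch)
  back_mlp <- function(v, h, go) {
    a <- h * (h > 0)
    layer$g_W2 <- layer$g_W2 + a %*% t(go)
    layer$g_b2 <- layer$g_b2 + rowSums(go)
    gh <- (layer$W2 %*% go) * (h > 0)
    layer$g_W1 <- layer$g_W1 + v %*% t(gh)
    layer$g_b1 <- layer$g_b1 + rowSums(gh)
    layer$W1 %*% gh
  }
  ggavg <- back_mlp(cc$gavg, cc$ha, go)
  ggmax <- back_mlp(cc$gmaxm, cc$hm, go)
  gx <- gx + gap2d_expand(ggavg / (d[2] * d[3]), d[2], d[3])
  for (n in seq_len(d[4])) {
    sl <- matrix(0, d[1], d[2] * d[3])
    sl[cbind(seq_len(d[1]), cc$idxm[, n])] <- ggmax[, n]
    gx[, , , n] <- gx[, , , n] + array(sl, d[1:3])
  }
  gx
}

# ---- coordinate attention ---------------------------------------------------

#' @rdname attention-blocks
#' @export
nn_ca <- function(ch, reduction = 16L) {
  mid <- max(8L, ch %/% reduction)
  b1 <- 1 / sqrt(ch)
  b2 <- 1 / sqrt(mid)
  l <- new_layer("ca",
                 W1 = matrix(stats::rnorm(ch * mid, 0, b1), ch, mid),
                 Wh = matrix(stats::rnorm(mid * ch, 0, b2), mid, ch),
                 Ww = matrix(stats::rnorm(mid * ch, 0, b2), mid, ch),
                 ch = ch, mid = mid)
  l$params <- c("W1", "Wh", "Ww")
  l$bn <- nn_batchnorm(mid)
  l
}

#' @export
nn_forward.nn_ca <- function(layer, x, ctx = nn_ctx()) {
  d <- dims4(x)
  ch <- d[1]; hh <- d[2]; ww <- d[3]; nn <- d[4]
  xh <- array(0, c(ch, hh, nn))  # mean over width
  xw <- array(0, c(ch, ww, nn))  # mean over height
  for (n in seq_len(nn)) {
    sl <- x[, , , n]
    xh[, , n] <- rowMeans(matrix(sl, ch * hh))
    xw[, , n] <- apply(sl, 3, function(m) rowMeans(matrix(m, ch)))
  }
  ycat <- array(0, c(ch, hh + ww, 1, nn))
  ycat[, seq_len(hh), 1, ] <- xh
  ycat[, hh + seq_len(ww), 1, ] <- xw
  mid_in <- crossprod(layer$W1, matrix(ycat, ch))
  mid4 <- array(mid_in, c(layer$mid, hh + ww, 1, nn))
  bn_out <- nn_forward(layer$bn, mid4, ctx)
  bs <- sigmoid(bn_out)
  act <- bn_out * bs
  ah_pre <- array(act[, seq_len(hh), 1, ], c(layer$mid, hh, nn))
  aw_pre <- array(act[, hh + seq_len(ww), 1, ], c(layer$mid, ww, nn))
  ah <- array(sigmoid(crossprod(layer$Wh, matrix(ah_pre, layer$mid))),
              c(ch, hh, nn))
  aw <- array(sigmoid(crossprod(layer$Ww, matrix(aw_pre, layer$mid))),
              c(ch, ww, nn))
  y <- x
  for (n in seq_len(nn)) {
    afull <- array(ah[, , n], c(ch, hh, ww))
    for (w in seq_len(ww)) afull[, , w] <- afull[, , w] * aw[, w, n]
    y[, , , n] <- x[, , , n] * afull
  }
  if (ctx$grad) {
    layer$cache <- list(x = x, ycat = ycat, bn_out = bn_out, bs = bs,
                        ah_pre = ah_pre, aw_pre = aw_pre, ah = ah, aw = aw)
  }
  y
}

#' @export
nn_backward.nn_ca <- function(layer, gy, ctx = nn_ctx(grad = TRUE)) {
  cc <- layer$cache
  layer$cache <- NULL
  d <- dims4(cc$x)
  ch <- d[1]; hh <- d[2]; ww <- d[3]; nn <- d[4]
  gx <- gy
  gah <- array(0, c(ch, hh, nn))
  gaw <- array(0, c(ch, ww, nn))
  p <- gy * cc$x
  for (n in seq_len(nn)) {
    afull <- array(cc$ah[, , n], c(ch, hh, ww))
    for (w in seq_len(ww)) afull[, , w] <- afull[, , w] * cc$aw[, w, n]
    gx[, , , n] <- gy[, , , n] * afull
    pn <- p[, , , n]
    # d/d ah[c,h] = sum_w p * aw[c,w];  d/d aw[c,w] = sum_h p * ah[c,h]
    paw <- pn
    for (w in seq_len(ww)) paw[, , w] <- paw[, , w] * cc$aw[, w, n]
    gah[, , n] <- rowSums(matrix(paw, ch * hh))
    pah <- pn * array(cc$ah[, , n], c(ch, hh, ww))
    gaw[, , n] <- apply(pah, 3, function(m) rowSums(matrix(m, ch)))
  }
  gah_pre_s <- gah * cc$ah * (1 - cc$ah)
  gaw_pre_s <- gaw * cc$aw * (1 - cc$aw)
  layer$g_Wh <- matrix(cc$ah_pre, layer$mid) %*% t(matrix(gah_pre_s, ch))
  layer$g_Ww <- matrix(cc$aw_pre, layer$mid) %*% t(matrix(gaw_pre_s, ch))
  gahp <- array(layer$Wh %*% matrix(gah_pre_s, ch), c(layer$mid, hh, nn))
  gawp <- array(layer$Ww %*% matrix(gaw_pre_s, ch), c(layer$mid, ww, nn))
  gact <- array(0, c(layer$mid, hh + ww, 1, nn))
  gact[, seq_len(hh), 1, ] <- gahp
  gact[, hh + seq_len(ww), 1, ] <- gawp
  gbn <- gact * swish_grad(cc$bn_out, cc$bs)
  gmid <- nn_backward(layer$bn, gbn, ctx)
  layer$g_W1 <- matrix(cc$ycat, ch) %*% t(matrix(gmid, layer$mid))
  gycat <- array(layer$W1 %*% matrix(gmid, layer$mid),
                 c(ch, hh + ww, 1, nn))
  gxh <- array(gycat[, seq_len(hh), 1, ], c(ch, hh, nn))
  gxw <- array(gycat[, hh + seq_len(ww), 1, ], c(ch, ww, nn))
  for (n in seq_len(nn)) {
    gx[, , , n] <- gx[, , , n] + array(rep(gxh[, , n] / ww, ww), c(ch, hh, ww))
    add_w <- array(0, c(ch, hh, ww))
    for (w in seq_len(ww)) add_w[, , w] <- gxw[, w, n] / hh
    gx[, , , n] <- gx[, , , n] + add_w
  }
  gx
}

# ---- LightCBAM (ECA channel gate + spatial gate, fused) --------------------

#' @rdname attention-blocks
#' @export
nn_lightcbam <- function(ch, variant = c("residual", "weighted", "tandem"),
                         eca_k = 3L, spatial_k = 7L, alpha_init = 0,
                         spatial_from = c("channel", "input")) {
  variant <- match.arg(variant)
  bound <- 1 / sqrt(eca_k)
  l <- new_layer("lightcbam",
                 w = stats::runif(eca_k, -bound, bound),
                 alpha_raw = alpha_init,
                 ch = ch, k = as.integer(eca_k), variant = variant,
                 spatial_from = match.arg(spatial_from))
  l$spconv <- spat_gate_init(spatial_k)
  l$params <- if (variant == "tandem") "w" else c("w", "alpha_raw")
  l
}

#' @export
nn_forward.nn_lightcbam <- function(layer, x, ctx = nn_ctx()) {
  d <- dims4(x)
  g <- gap2d(x)
  cv <- conv1d_channels(g, layer$w)
  wc <- sigmoid(cv$z)
  fc <- bcast_cmul(x, wc)
  base <- if (layer$spatial_from == "channel") fc else x
  s <- spat_gate_forward(layer, base, ctx)
  fs <- bcast_smul(fc, s)
  a <- sigmoid(layer$alpha_raw)
  y <- switch(layer$variant,
              tandem = fs,
              weighted = a * fc + (1 - a) * fs,
              residual = a * fc + (1 - a) * fs + x)
  if (ctx$grad) {
    layer$cache <- list(x = x, gp = cv$gp, wc = wc, fc = fc, s = s, fs = fs,
                        a = a)
  }
  y
}

#' @export
nn_backward.nn_lightcbam <- function(layer, gy, ctx = nn_ctx(grad = TRUE)) {
  cc <- layer$cache
  layer$cache <- NULL
  d <- dims4(cc$x)
  if (layer$variant == "tandem") {
    gfc_direct <- 0
    gfs <- gy
  } else {
    gfc_direct <- cc$a * gy
    gfs <- (1 - cc$a) * gy
    layer$g_alpha_raw <- sum(gy * (cc$fc - cc$fs)) * cc$a * (1 - cc$a)
  }
  gfc <- bcast_smul(gfs, cc$s) + gfc_direct
  gs <- sgate_sum(gfs, cc$fc)
  gbase <- spat_gate_backward(layer, gs)
  gx_sp <- 0
  if (layer$spatial_from == "channel") gfc <- gfc + gbase else gx_sp <- gbase
  gwc <- cgate_sum(gfc, cc$x)
  gx <- bcast_cmul(gfc, cc$wc)
  gz <- gwc * cc$wc * (1 - cc$wc)
  k <- layer$k
  gw <- numeric(k)
  for (j in seq_len(k)) {
    gw[j] <- sum(cc$gp[j:(j + d[1] - 1L), , drop = FALSE] * gz)
  }
  layer$g_w <- gw
  gg <- conv1d_channels(gz, rev(layer$w))$z
  gx <- gx + gap2d_expand(gg / (d[2] * d[3]), d[2], d[3]) + gx_sp
  if (layer$variant == "residual") gx <- gx + gy
  gx
}

make_attention <- function(kind, ch, ch_base, cfg = list()) {
  kind <- match.arg(kind, c("none", "se", "eca", "cbam", "ca",
                            "lightcbam_tandem", "lightcbam_weighted",
                            "lightcbam_residual"))
  eca_k <- cfg$eca_kernel %||% 3L
  sp_k <- cfg$spatial_kernel %||% 7L
  switch(kind,
         none = nn_identity(),
         se = nn_se(ch, ch_base, cfg$se_ratio %||% 0.25),
         eca = nn_eca(ch, eca_k),
         cbam = nn_cbam(ch, cfg$reduction %||% 16L, sp_k),
         ca = nn_ca(ch, cfg$reduction %||% 16L),
         lightcbam_tandem = nn_lightcbam(ch, "tandem", eca_k, sp_k,
                                         cfg$alpha_init %||% 0,
                                         cfg$spatial_from %||% "channel"),
         lightcbam_weighted = nn_lightcbam(ch, "weighted", eca_k, sp_k,
                                           cfg$alpha_init %||% 0,
                                           cfg$spatial_from %||% "channel"),
         lightcbam_residual = nn_lightcbam(ch, "residual", eca_k, sp_k,
                                           cfg$alpha_init %||% 0,
                                           cfg$spatial_from %||% "channel"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
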