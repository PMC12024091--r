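# Minimal CNN engine: layers are mutable environments holding weights,
# gradients and forward caches; backward passes are hand-derived and
# verified against finite differences in the test suite.
#
# Batch layout throughout: numeric array dim (C, H, W, N), channel fastest,
# so per-channel broadcasts use R's first-dimension recycling for free.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- character(0)
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

#' Create a forward/backward context for engine layers
#'
#' @param training Use batch statistics and enable gradient caching.
#' @param grad Store caches needed for a subsequent backward pass.
#' @param trace Record every named sub-block's activations and gradients.
#' @return A context environment passed to [nn_forward()]/[nn_backward()].
#' @export
nn_ctx <- function(training = FALSE, grad = training, trace = FALSE) {
  ctx <- new.env(parent = emptyenv())
  ctx$training <- training
  ctx$grad <- grad
  ctx$trace <- trace
  if (trace) {
    ctx$acts <- new.env(parent = emptyenv())
    ctx$grads <- new.env(parent = emptyenv())
  }
  ctx$prefix <- ""
  ctx
}

#' Run a layer (or composite block) forward
#'
#' @param layer An engine layer created by one of the `nn_*` constructors.
#' @param x Input array `(C, H, W, N)` (or a matrix for dense layers).
#' @param ctx A [nn_ctx()] context.
#' @return The layer output.
#' @export
nn_forward <- function(layer, x, ctx = nn_ctx()) UseMethod("nn_forward")
#' Backpropagate through a layer (or composite block)
#'
#' Requires a preceding [nn_forward()] call with gradient caching enabled;
#' parameter gradients are stored in the layer as `g_<name>` fields.
#'
#' @param layer An engine layer.
#' @param gy Gradient of the loss with respect to the layer output.
#' @param ctx A [nn_ctx()] context.
#' @return Gradient with respect to the layer input.
#' @export
nn_backward <- function(layer, gy, ctx = nn_ctx(grad = TRUE)) UseMethod("nn_backward")

#' @noRd
nn_leaves <- function(layer) {
  if (!is.null(layer$children)) {
    return(unlist(lapply(layer$children, nn_leaves),
                  recursive = FALSE, use.names = FALSE))
  }
  out <- list(layer)
  # attention blocks embed auxiliary layers outside the children list
  if (!is.null(layer$spconv)) out <- c(out, list(layer$spconv))
  if (!is.null(layer$bn)) out <- c(out, list(layer$bn))
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

dims4 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  d
}

as_batch <- function(x) {
  # accepts (C,H,W) or (C,H,W,N)
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

# ---- broadcast helpers (thin wrappers over the C++ kernels) ----------------

# multiply x (C,H,W,N) by per-sample channel weights s (C,N)
bcast_cmul <- function(x, s) {
  d <- dims4(x)
  cb_cmul(x, s, d[1], d[2], d[3], d[4])
}

# grad of the channel gate: sum over H,W of gy * x  -> (C,N)
cgate_sum <- function(gy, x) {
  d <- dims4(x)
  cb_cmul_sum(gy, x, d[1], d[2], d[3], d[4])
}

# multiply x (C,H,W,N) by per-sample spatial map s (H,W,N)
bcast_smul <- function(x, s) {
  d <- dims4(x)
  cb_smul(x, s, d[1], d[2], d[3], d[4])
}

# grad of the spatial gate: sum over channels of gy * x -> (H,W,N)
sgate_sum <- function(gy, x) {
  d <- dims4(x)
  cb_smul_sum(gy, x, d[1], d[2], d[3], d[4])
}

# per-(channel, sample) spatial mean -> (C, N)
gap2d <- function(x) {
  d <- dims4(x)
  cb_gap2d(x, d[1], d[2], d[3], d[4])
}

# expand per-(channel,sample) values g (C,N) evenly over H x W
gap2d_expand <- function(g, h, w) {
  cb_gap_expand(g, h, w)
}

# ---- weight init ------------------------------------------------------------

kaiming_conv <- function(cin, k, cout) {
  fan_out <- k * k * cout
  array(stats::rnorm(cin * k * k * cout, 0, sqrt(2 / fan_out)),
        c(cin, k, k, cout))
}

# ---- conv2d (dense, square kernel, "same"-style zero padding) --------------

#' Engine layers: dense and depthwise convolution, batch norm, activations,
#' pooling, linear
#'
#' Constructors for the minimal CNN engine underlying the backbone.  All
#' layers operate on `(C, H, W, N)` arrays (channel fastest) and implement
#' exact hand-derived backward passes.
#'
#' @param cin,cout,ch Input/output channel counts.
#' @param k Square kernel size.
#' @param stride,pad Convolution stride and zero padding.
#' @param bias Include a bias vector.
#' @param eps,momentum Batch-norm stabilizer and running-average momentum.
#' @param din,dout Linear layer input/output sizes.
#' @return An engine layer (a mutable environment).
#' @name engine-layers
NULL

#' @rdname engine-layers
#' @export
nn_conv2d <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                      bias = FALSE) {
  l <- new_layer("conv2d",
                 W = kaiming_conv(cin, k, cout),
                 cin = cin, cout = cout, k = as.integer(k),
                 stride = as.integer(stride), pad = as.integer(pad))
  l$params <- "W"
  if (bias) {
    l$b <- numeric(cout)
    l$params <- c("W", "b")
  }
  l
}

#' @export
nn_forward.nn_conv2d <- function(layer, x, ctx = nn_ctx()) {
  d <- dims4(x)
  cols <- cb_im2col(x, d[1], d[2], d[3], d[4], layer$k, layer$stride, layer$pad)
  wm <- matrix(layer$W, nrow = layer$cin * layer$k^2)
  y <- crossprod(wm, cols)
  if (!is.null(layer$b)) y <- y + layer$b
  oh <- (d[2] + 2 * layer$pad - layer$k) %/% layer$stride + 1L
  ow <- (d[3] + 2 * layer$pad - layer$k) %/% layer$stride + 1L
  dim(y) <- c(layer$cout, oh, ow, d[4])
  if (ctx$grad) {
    layer$cache <- list(cols = cols, din = d)
  }
  y
}

#' @export
nn_backward.nn_conv2d <- function(layer, gy, ctx = nn_ctx(grad = TRUE)) {
  cc <- layer$cache
  g <- matrix(gy, nrow = layer$cout)
  wm <- matrix(layer$W, nrow = layer$cin * layer$k^2)
  gw <- tcrossprod(cc$cols, g)
  layer$g_W <- array(gw, dim(layer$W))
  if (!is.null(layer$b)) layer$g_b <- rowSums(g)
  gcols <- wm %*% g
  gx <- cb_col2im(gcols, cc$din[1], cc$din[2], cc$din[3], cc$din[4],
                  layer$k, layer$stride, layer$pad)
  layer$cache <- NULL
  gx
}

# ---- depthwise conv2d -------------------------------------------------------

#' @rdname engine-layers
#' @export
nn_dwconv2d <- function(ch, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  fan_out <- k * k
  l <- new_layer("dwconv2d",
                 W = array(stats::rnorm(k * k * ch, 0, sqrt(2 / fan_out)),
                           c(k, k, ch)),
                 ch = ch, k = as.integer(k),
                 stride = as.integer(stride), pad = as.integer(pad))
  l$params <- "W"
  l
}

#' @export
nn_forward.nn_dwconv2d <- function(layer, x, ctx = nn_ctx()) {
  d <- dims4(x)
  y <- cb_dwconv_fwd(x, d[1], d[2], d[3], d[4], layer$W, layer$k,
                     layer$stride, layer$pad)
  if (ctx$grad) layer$cache <- list(x = x, din = d)
  y
}

#' @export
nn_backward.nn_dwconv2d <- function(layer, gy, ctx = nn_ctx(grad = TRUE)) {
  cc <- layer$cache
  d <- cc$din
  layer$g_W <- cb_dwconv_bwd_weight(cc$x, gy, d[1], d[2], d[3], d[4],
                                    layer$k, layer$stride, layer$pad)
  gx <- cb_dwconv_bwd_data(gy, d[1], d[2], d[3], d[4], layer$W, layer$k,
                           layer$stride, layer$pad)
  layer$cache <- NULL
  gx
}

# ---- batch norm -------------------------------------------------------------

#' @rdname engine-layers
#' @export
nn_batchnorm <- function(ch, eps = 1e-3, momentum = 0.1) {
  l <- new_layer("batchnorm",
                 gamma = rep(1, ch), beta = numeric(ch),
                 running_mean = numeric(ch), running_var = rep(1, ch),
                 ch = ch, eps = eps, momentum = momentum)
  l$params <- c("gamma", "beta")
  l
}

#' @export
nn_forward.nn_batchnorm <- function(layer, x, ctx = nn_ctx()) {
  d <- dims4(x)
  cc <- d[1]
  if (ctx$training) {
    m <- as.vector(cb_gap2d(x, cc, d[2], d[3] * d[4], 1L))
    xhat0 <- cb_chan_affine(x, rep(1, cc), -m, cc)
    v <- as.vector(cb_gap2d(xhat0 * xhat0, cc, d[2], d[3] * d[4], 1L))
    inv <- 1 / sqrt(v + layer$eps)
    xhat <- cb_chan_affine(x, inv, -m * inv, cc)
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
      layer$momentum * m
    layer$running_var <- (1 - layer$momentum) * layer$running_var +
      layer$momentum * v
  } else {
    inv <- 1 / sqrt(layer$running_var + layer$eps)
    xhat <- cb_chan_affine(x, inv, -layer$running_mean * inv, cc)
  }
  y <- cb_chan_affine(xhat, layer$gamma, layer$beta, cc)
  if (ctx$grad) {
    layer$cache <- list(xhat = xhat, inv = inv, din = d,
                        batch_stats = ctx$training)
  }
  y
}

#' @export
nn_backward.nn_batchnorm <- function(layer, gy, ctx = nn_ctx(grad = TRUE)) {
  cc <- layer$cache
  ch <- cc$din[1]
  sp <- c(cc$din[2], cc$din[3] * cc$din[4])
  xhat <- cc$xhat
  m <- prod(cc$din[-1])
  layer$g_gamma <- as.vector(cb_gap2d(gy * xhat, ch, sp[1], sp[2], 1L)) * m
  layer$g_beta <- as.vector(cb_gap2d(gy, ch, sp[1], sp[2], 1L)) * m
  gxhat <- cb_chan_affine(gy, layer$gamma, numeric(ch), ch)
  if (cc$batch_stats) {
    s1 <- as.vector(cb_gap2d(gxhat, ch, sp[1], sp[2], 1L))
    s2 <- as.vector(cb_gap2d(gxhat * xhat, ch, sp[1], sp[2], 1L))
    gx <- cb_chan_affine(gxhat, cc$inv, -cc$inv * s1, ch) -
      cb_chan_affine(xhat, cc$inv * s2, numeric(ch), ch)
  } else {
    gx <- cb_chan_affine(gxhat, cc$inv, numeric(ch), ch)
  }
  layer$cache <- NULL
  gx
}

# ---- activations ------------------------------------------------------------

#' @rdname engine-layers
#' @export
nn_swish <- function() new_layer("swish")

#' @export
nn_forward.nn_swish <- function(layer, x, ctx = nn_ctx()) {
  res <- cb_swish_fwd(x)
  if (ctx$grad) layer$cache <- list(x = x, s = res$s)
  res$y
}

#' @export
nn_backward.nn_swish <- function(layer, gy, ctx = nn_ctx(grad = TRUE)) {
  cc <- layer$cache
  layer$cache <- NULL
  cb_swish_bwd(gy, cc$x, cc$s)
}

#' @rdname engine-layers
#' @export
nn_relu <- function() new_layer("relu")

#' @export
nn_forward.nn_relu <- function(layer, x, ctx = nn_ctx()) {
  if (ctx$grad) layer$cache <- list(pos = x > 0)
  x * (x > 0)
}

#' @export
nn_backward.nn_relu <- function(layer, gy, ctx = nn_ctx(grad = TRUE)) {
  cc <- layer$cache
  layer$cache <- NULL
  gy * cc$pos
}

# ---- global average pooling (C,H,W,N) -> (C,N) -----------------------------

#' @rdname engine-layers
#' @export
nn_gap <- function() new_layer("gap")

#' @export
nn_forward.nn_gap <- function(layer, x, ctx = nn_ctx()) {
  d <- dims4(x)
  if (ctx$grad) layer$cache <- list(din = d)
  gap2d(x)
}

#' @export
nn_backward.nn_gap <- function(layer, gy, ctx = nn_ctx(grad = TRUE)) {
  d <- layer$cache$din
  layer$cache <- NULL
  gap2d_expand(gy / (d[2] * d[3]), d[2], d[3])
}

# ---- linear (in,N) -> (out,N) ----------------------------------------------

#' @rdname engine-layers
#' @export
nn_linear <- function(din, dout) {
  bound <- 1 / sqrt(din)
  l <- new_layer("linear",
                 W = matrix(stats::runif(din * dout, -bound, bound), din, dout),
                 b = stats::runif(dout, -bound, bound),
                 din = din, dout = dout)
  l$params <- c("W", "b")
  l
}

#' @export
nn_forward.nn_linear <- function(layer, x, ctx = nn_ctx()) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (ctx$grad) layer$cache <- list(x = x)
  crossprod(layer$W, x) + layer$b
}

#' @export
nn_backward.nn_linear <- function(layer, gy, ctx = nn_ctx(grad = TRUE)) {
  cc <- layer$cache
  layer$cache <- NULL
  layer$g_W <- cc$x %*% t(gy)
  layer$g_b <- rowSums(gy)
  layer$W %*% gy
}

# ---- identity ---------------------------------------------------------------

#' @rdname engine-layers
#' @export
nn_identity <- function() new_layer("identity")

#' @export
nn_forward.nn_identity <- function(layer, x, ctx = nn_ctx()) x

#' @export
nn_backward.nn_identity <- function(layer, gy, ctx = nn_ctx(grad = TRUE)) gy

# ---- sequential container ---------------------------------------------------

nn_sequential <- function(children) {
  stopifnot(is.list(children))
  if (is.null(names(children)) || any(!nzchar(names(children)))) {
    names(children) <- sprintf("l%d", seq_along(children))
  }
  new_layer("sequential", children = children)
}

#' @export
nn_forward.nn_sequential <- function(layer, x, ctx = nn_ctx()) {
  pfx <- ctx$prefix
  for (nm in names(layer$children)) {
    ctx$prefix <- if (nzchar(pfx)) paste0(pfx, ".", nm) else nm
    x <- nn_forward(layer$children[[nm]], x, ctx)
    if (ctx$trace) assign(ctx$prefix, x, envir = ctx$acts)
  }
  ctx$prefix <- pfx
  x
}

#' @export
nn_backward.nn_sequential <- function(layer, gy, ctx = nn_ctx(grad = TRUE)) {
  pfx <- ctx$prefix
  for (nm in rev(names(layer$children))) {
    ctx$prefix <- if (nzchar(pfx)) paste0(pfx, ".", nm) else nm
    if (ctx$trace) assign(ctx$prefix, gy, envir = ctx$grads)
    gy <- nn_backward(layer$children[[nm]], gy, ctx)
  }
  ctx$prefix <- pfx
  gy
}

# ---- residual wrapper: y = f(x) + x when enabled ---------------------------

nn_residual <- function(body, shortcut = TRUE) {
  new_layer("residual", children = list(body = body), shortcut = shortcut)
}

#' @export
nn_forward.nn_residual <- function(layer, x, ctx = nn_ctx()) {
  y <- nn_forward(layer$children$body, x, ctx)
  if (layer$shortcut) y <- y + x
  y
}

#' @export
nn_backward.nn_residual <- function(layer, gy, ctx = nn_ctx(grad = TRUE)) {
  gx <- nn_backward(layer$children$body, gy, ctx)
  if (layer$shortcut) gx <- gx + gy
  gx
}
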