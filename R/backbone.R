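# CowBackNet backbone: an EfficientNetV2-style trunk whose inverted-residual
# blocks host a swappable attention module (LightCBAM by default), built from
# a declarative 8-stage specification.

#' Stage specification
#'
#' One row of the backbone's stage table: which block operator a stage uses,
#' its sub-convolution kernels and strides, the per-sub-convolution channel
#' list for the stage's first block, the stage's output resolution at
#' 224-pixel input, and how many blocks the stage repeats.
#'
#' @param operator One of `"conv_module"`, `"enhanced_conv_module"`,
#'   `"edge_residual"`, `"inverted_residual"`.
#' @param kernel_sizes Integer vector, one (square) kernel size per
#'   sub-convolution.
#' @param resolution Output spatial size `(h, w)` at 224-pixel input.
#' @param strides Integer vector of strides, same length as `kernel_sizes`.
#' @param channels Integer vector of output channels per sub-convolution.
#' @param layers Number of repeated blocks in the stage.
#' @return A `stage_spec` list.
#' @export
stage_spec <- function(operator, kernel_sizes, resolution, strides, channels,
                       layers = 1L) {
  operator <- match.arg(operator, c("conv_module", "enhanced_conv_module",
                                    "edge_residual", "inverted_residual"))
  stopifnot(layers >= 1, length(channels) >= 1,
            length(kernel_sizes) == length(strides))
  structure(list(operator = operator,
                 kernel_sizes = as.integer(kernel_sizes),
                 resolution = as.integer(resolution),
                 strides = as.integer(strides),
                 channels = as.integer(channels),
                 layers = as.integer(layers)),
            class = "stage_spec")
}

#' Default CowBackNet architecture specification
#'
#' The 8-stage backbone: a stride-2 stem expanding 3 to 32 channels, an
#' enhanced convolution stage, two edge-residual (fused-conv) stages, three
#' inverted-residual stages hosting the attention module, and a 1x1
#' convolution head producing a 1280-channel, 7x7 feature map that is
#' average-pooled into the embedding.
#'
#' @param num_classes Number of identities for the classifier head
#'   (default 22).
#' @param attention Attention mechanism inside inverted-residual blocks; one
#'   of `"lightcbam_residual"` (default), `"lightcbam_weighted"`,
#'   `"lightcbam_tandem"`, `"se"`, `"eca"`, `"cbam"`, `"ca"`, `"none"`.
#' @param width_mult Channel width multiplier for desk-scale models
#'   (default 1 = full width; channels are rounded to multiples of 4).
#' @param input_size Input spatial size, default `c(224, 224)`.
#' @param attention_cfg Optional list of attention hyperparameters
#'   (`eca_kernel`, `spatial_kernel`, `alpha_init`, `se_ratio`, `reduction`,
#'   `spatial_from`).
#' @return An `architecture_spec` list.
#' @export
default_cowbacknet_spec <- function(num_classes = 22L,
                                    attention = "lightcbam_residual",
                                    width_mult = 1,
                                    input_size = c(224L, 224L),
                                    attention_cfg = list()) {
  stages <- list(
    stage_spec("conv_module", 3L, c(224L, 224L), 2L, 32L, 1L),
    stage_spec("enhanced_conv_module", 3L, c(112L, 112L), 1L, 16L, 1L),
    stage_spec("edge_residual", c(3L, 1L), c(112L, 112L), c(2L, 1L),
               c(64L, 32L), 2L),
    stage_spec("edge_residual", c(3L, 1L), c(56L, 56L), c(2L, 1L),
               c(128L, 48L), 2L),
    stage_spec("inverted_residual", c(1L, 3L, 1L), c(28L, 28L),
               c(1L, 2L, 1L), c(192L, 192L, 96L), 3L),
    stage_spec("inverted_residual", c(1L, 3L, 1L), c(14L, 14L),
               c(1L, 1L, 1L), c(576L, 576L, 112L), 5L),
    stage_spec("inverted_residual", c(1L, 3L, 1L), c(7L, 7L),
               c(1L, 2L, 1L), c(672L, 672L, 192L), 8L),
    stage_spec("conv_module", 1L, c(7L, 7L), 1L, 1280L, 1L)
  )
  structure(list(stages = stages, embedding_dim = 1280L,
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 attention = attention, attention_cfg = attention_cfg,
                 width_mult = width_mult,
                 norm_mean = 0.5, norm_sd = 0.5),
            class = "architecture_spec")
}

#' Reduced-width CowBackNet specification for desk-scale experiments
#'
#' Same stage structure as [default_cowbacknet_spec()] with channels scaled
#' by `width_mult` and a smaller input, sized so a full training run on a
#' synthetic herd finishes in minutes on one CPU core.
#'
#' @inheritParams default_cowbacknet_spec
#' @export
small_cowbacknet_spec <- function(num_classes = 10L,
                                  attention = "lightcbam_residual",
                                  width_mult = 0.25,
                                  input_size = c(48L, 48L),
                                  attention_cfg = list()) {
  default_cowbacknet_spec(num_classes = num_classes, attention = attention,
                          width_mult = width_mult, input_size = input_size,
                          attention_cfg = attention_cfg)
}

scale_ch <- function(ch, wm, divisor = 4L) {
  if (wm == 1) return(as.integer(ch))
  as.integer(pmax(divisor, round(ch * wm / divisor) * divisor))
}

validate_spec <- function(spec) {
  res <- 224L
  for (i in seq_along(spec$stages)) {
    st <- spec$stages[[i]]
    if (length(st$kernel_sizes) != length(st$strides)) {
      stop("stage ", i - 1L, ": kernel/stride lists differ in length")
    }
    res <- res %/% prod(st$strides)
  }
  if (res != 7L) {
    stop("stage strides do not reduce 224 to the 7x7 head resolution")
  }
  invisible(spec)
}

cbs <- function(cin, cout, k, stride = 1L) {
  nn_sequential(list(conv = nn_conv2d(cin, cout, k, stride),
                     bn = nn_batchnorm(cout),
                     act = nn_swish()))
}

edge_block <- function(cin, cexp, cout, k, stride) {
  body <- nn_sequential(list(
    expand = nn_conv2d(cin, cexp, k[1], stride[1]),
    bn1 = nn_batchnorm(cexp),
    act1 = nn_swish(),
    project = nn_conv2d(cexp, cout, k[2], stride[2]),
    bn2 = nn_batchnorm(cout)))
  nn_residual(body, shortcut = all(stride == 1L) && cin == cout)
}

mbconv_block <- function(cin, cexp, cout, k, stride, attention,
                         attention_cfg) {
  body <- nn_sequential(list(
    expand = nn_conv2d(cin, cexp, k[1], stride[1]),
    bn1 = nn_batchnorm(cexp),
    act1 = nn_swish(),
    dw = nn_dwconv2d(cexp, k[2], stride[2]),
    bn2 = nn_batchnorm(cexp),
    act2 = nn_swish(),
    attn = make_attention(attention, cexp, cin, attention_cfg),
    project = nn_conv2d(cexp, cout, k[3], stride[3]),
    bn3 = nn_batchnorm(cout)))
  nn_residual(body, shortcut = all(stride == 1L) && cin == cout)
}

build_stage <- function(st, cin, wm, attention, attention_cfg, stage_idx) {
  ch <- scale_ch(st$channels, wm)
  blocks <- list()
  cur <- cin
  for (b in seq_len(st$layers)) {
    stride <- if (b == 1L) st$strides else rep(1L, length(st$strides))
    blk <- switch(st$operator,
      conv_module = cbs(cur, ch[1], st$kernel_sizes[1], stride[1]),
      enhanced_conv_module = {
        body <- cbs(cur, ch[1], st$kernel_sizes[1], stride[1])
        nn_residual(body, shortcut = stride[1] == 1L && cur == ch[1])
      },
      edge_residual = {
        cexp <- if (b == 1L) ch[1] else {
          ratio <- round(st$channels[1] / cin_ratio_base(st, cin, wm))
          scale_ch(st$channels[2], wm) * ratio
        }
        edge_block(cur, cexp, ch[2], st$kernel_sizes, stride)
      },
      inverted_residual = {
        cexp <- if (b == 1L) ch[1] else {
          ratio <- round(st$channels[1] / cin_ratio_base(st, cin, wm))
          scale_ch(st$channels[3], wm) * ratio
        }
        mbconv_block(cur, cexp, ch[length(ch)], st$kernel_sizes, stride,
                     attention, attention_cfg)
      },
      stop("stage ", stage_idx, ": unknown operator ", st$operator))
    cur <- ch[length(ch)]
    blocks[[sprintf("block%d", b)]] <- blk
  }
  if (length(blocks) == 1L) blocks[[1]] else nn_sequential(blocks)
}

# expansion ratios are read off the printed table relative to the stage's
# *input* channels at full width (e.g. 576/96 = 6)
cin_ratio_base <- function(st, cin_scaled, wm) {
  # reconstruct the unscaled input channels from the table is not possible
  # locally; callers pass the unscaled value through the attribute below
  attr(st, "cin_full")
}

#' Build a CowBackNet model
#'
#' Instantiates the network described by an [default_cowbacknet_spec()]
#' specification with reproducible random initial weights.
#'
#' @param spec An `architecture_spec`.
#' @param seed Integer seed controlling weight initialization.
#' @return A `cow_model` object with named sub-blocks addressable for
#'   Grad-CAM and complexity accounting.
#' @export
build_model <- function(spec, seed = 1L) {
  validate_spec(spec)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  wm <- spec$width_mult
  stages <- list()
  cin <- 3L
  cin_full <- 3L
  full <- c(3L, vapply(spec$stages,
                       function(s) s$channels[length(s$channels)], 1L))
  for (i in seq_along(spec$stages)) {
    st <- spec$stages[[i]]
    attr(st, "cin_full") <- full[i]
    nm <- sprintf("stage%d", i - 1L)
    if (i == length(spec$stages)) {
      # head conv outputs the embedding dimension
      emb <- scale_ch(spec$embedding_dim, wm, 8L)
      stages[[nm]] <- cbs(cin, emb, st$kernel_sizes[1], st$strides[1])
      cin <- emb
    } else {
      stages[[nm]] <- build_stage(st, cin, wm, spec$attention,
                                  spec$attention_cfg, i - 1L)
      cin <- scale_ch(st$channels[length(st$channels)], wm)
    }
  }
  stages$pool <- nn_gap()
  m <- new.env(parent = emptyenv())
  m$spec <- spec
  m$embedding_dim <- cin
  m$features <- nn_sequential(stages)
  m$classifier <- nn_linear(cin, spec$num_classes)
  m$net <- nn_sequential(list(features = m$features, fc = m$classifier))
  m$seed <- seed
  class(m) <- "cow_model"
  m
}

#' Build an EfficientNetV2-style baseline with a chosen attention mechanism
#'
#' The unmodified baseline keeps squeeze-and-excitation (SE) attention in
#' every inverted-residual block; the other variants swap SE for coordinate
#' attention, CBAM, or efficient channel attention, leaving the layer graph
#' otherwise identical.
#'
#' @param variant One of `"effv2"`, `"effv2_ca"`, `"effv2_cbam"`,
#'   `"effv2_eca"`.
#' @param num_classes Classifier width; complexity comparisons use the
#'   1000-class reference head (the default).
#' @param seed Integer seed for weight initialization.
#' @param width_mult,input_size As in [default_cowbacknet_spec()].
#' @return A `cow_model`.
#' @export
build_baseline <- function(variant = c("effv2", "effv2_ca", "effv2_cbam",
                                       "effv2_eca"),
                           num_classes = 1000L, seed = 1L, width_mult = 1,
                           input_size = c(224L, 224L)) {
  variant <- match.arg(variant)
  attn <- switch(variant, effv2 = "se", effv2_ca = "ca",
                 effv2_cbam = "cbam", effv2_eca = "eca")
  spec <- default_cowbacknet_spec(num_classes = num_classes,
                                  attention = attn, width_mult = width_mult,
                                  input_size = input_size)
  build_model(spec, seed)
}

normalize_input <- function(m, x) {
  (x - m$spec$norm_mean) / m$spec$norm_sd
}

#' Compute embeddings for a batch of images
#'
#' @param m A `cow_model`.
#' @param x Numeric array `(3, H, W, N)` (or `(3, H, W)`) with values in
#'   `[0, 1]`; `H`, `W` must match the model's configured input size.
#'   Normalization to the model's fixed channel mean/sd happens internally.
#' @return Matrix `N x embedding_dim` of pooled features.
#' @export
forward_features <- function(m, x) {
  x <- as_batch(x)
  d <- dims4(x)
  if (d[2] != m$spec$input_size[1] || d[3] != m$spec$input_size[2]) {
    stop("input is ", d[2], "x", d[3], " but the model expects ",
         m$spec$input_size[1], "x", m$spec$input_size[2])
  }
  emb <- nn_forward(m$features, normalize_input(m, x), nn_ctx())
  t(emb)
}

#' Compute class logits for a batch of images
#'
#' @inheritParams forward_features
#' @return Matrix `N x num_classes` of logits; `argmax` along a row is the
#'   top-1 prediction.
#' @export
classify <- function(m, x) {
  x <- as_batch(x)
  emb <- t(forward_features(m, x))
  t(nn_forward(m$classifier, emb, nn_ctx()))
}

#' Per-stage resolution chain of a specification
#'
#' @param spec An `architecture_spec`.
#' @param input_size Input spatial side (default from the spec).
#' @return Data frame with one row per stage: input and output side length.
#' @export
resolution_chain <- function(spec, input_size = spec$input_size[1]) {
  res <- input_size
  out <- data.frame(stage = sprintf("stage%d", seq_along(spec$stages) - 1L),
                    input = NA_integer_, output = NA_integer_)
  for (i in seq_along(spec$stages)) {
    out$input[i] <- res
    res <- res %/% as.integer(prod(spec$stages[[i]]$strides))
    out$output[i] <- res
  }
  out
}

#' Names of the addressable sub-blocks of a model
#'
#' @param m A `cow_model`.
#' @return Character vector of dotted layer paths, usable as Grad-CAM
#'   targets.
#' @export
model_layer_names <- function(m) {
  walk <- function(layer, prefix) {
    if (is.null(layer$children)) return(prefix)
    out <- prefix
    for (nm in names(layer$children)) {
      child_prefix <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
      out <- c(out, walk(layer$children[[nm]], child_prefix))
    }
    out
  }
  setdiff(walk(m$net, ""), "")
}

#' @export
print.cow_model <- function(x, ...) {
  cat(sprintf("<cow_model> attention=%s width_mult=%g input=%dx%d classes=%d\n",
              x$spec$attention, x$spec$width_mult, x$spec$input_size[1],
              x$spec$input_size[2], x$spec$num_classes))
  cat(sprintf("  embedding: %d  parameters: %.3f M\n", x$embedding_dim,
              count_params(x)))
  invisible(x)
}
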