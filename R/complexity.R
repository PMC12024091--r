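# Parameter and FLOP accounting.
#
# Two conventions are exposed for model totals:
#   * "macs"  (default): h*w*(cin*K^2 + 1)*cout per dense convolution --
#     one multiply-accumulate per kernel tap, the scale on which published
#     complexity tables for these backbones are printed;
#   * "doubled": the same expression times 2, counting multiplies and adds
#     separately.
# Depthwise convolutions are counted per group (cin = 1 inside the formula),
# linear layers as (in+1)*out, attention-internal pooling/gating at their
# multiply-add cost; batch normalization and activations are excluded.
# h and w are the *output* spatial size of each convolution, the only
# reading that reproduces standard totals for strided layers.

#' FLOPs of a single dense convolution
#'
#' The literal formula `2 h w (c_in K^2 + 1) c_out`, with `h`, `w` the
#' output spatial size.
#'
#' @param h,w Output height and width in pixels.
#' @param c_in,c_out Input and output channel counts.
#' @param K Square kernel width.
#' @return FLOP count as a double.
#' @export
#' @examples
#' conv_flops(1, 1, 1, 1, 1)        # 4
#' conv_flops(112, 112, 3, 32, 3)   # 22478848
conv_flops <- function(h, w, c_in, c_out, K) {
  vals <- c(h = h, w = w, c_in = c_in, c_out = c_out, K = K)
  if (any(!is.finite(vals)) || any(vals < 1)) {
    stop("all convolution shape fields must be positive, got ",
         paste(sprintf("%s=%s", names(vals), vals), collapse = ", "),
         call. = FALSE)
  }
  2 * h * w * (c_in * K^2 + 1) * c_out
}

conv_macs <- function(h, w, c_in, c_out, K, groups = 1L) {
  # per-group application of the conv formula on the multiply-accumulate scale
  h * w * (c_in / groups * K^2 + 1) * c_out
}

n_params <- function(layer) {
  sum(vapply(layer$params, function(p) length(layer[[p]]), 1))
}

cx_rows <- function(layer, name, h, w, convention) {
  mult <- if (convention == "doubled") 2 else 1
  row <- function(nm, params, flops, h2 = h, w2 = w) {
    list(rows = data.frame(layer = nm, type = class(layer)[1],
                           params = params, flops = flops * mult),
         h = h2, w = w2)
  }
  empty <- list(rows = NULL, h = h, w = w)
  if (!is.null(layer$children)) {
    rows <- NULL
    if (inherits(layer, "nn_residual")) {
      res <- cx_rows(layer$children$body, name, h, w, convention)
      return(res)
    }
    for (nm in names(layer$children)) {
      child <- layer$children[[nm]]
      cn <- if (nzchar(name)) paste0(name, ".", nm) else nm
      res <- cx_rows(child, cn, h, w, convention)
      rows <- rbind(rows, res$rows)
      h <- res$h; w <- res$w
    }
    return(list(rows = rows, h = h, w = w))
  }
  switch(class(layer)[1],
    nn_conv2d = {
      oh <- (h + 2 * layer$pad - layer$k) %/% layer$stride + 1L
      ow <- (w + 2 * layer$pad - layer$k) %/% layer$stride + 1L
      row(name, n_params(layer),
          conv_macs(oh, ow, layer$cin, layer$cout, layer$k), oh, ow)
    },
    nn_dwconv2d = {
      oh <- (h + 2 * layer$pad - layer$k) %/% layer$stride + 1L
      ow <- (w + 2 * layer$pad - layer$k) %/% layer$stride + 1L
      row(name, n_params(layer),
          conv_macs(oh, ow, layer$ch, layer$ch, layer$k, groups = layer$ch),
          oh, ow)
    },
    nn_batchnorm = row(name, n_params(layer), 0),
    nn_linear = row(name, n_params(layer), (layer$din + 1) * layer$dout),
    nn_gap = row(name, 0, NA_real_, 1L, 1L),  # pooling cost folded below
    nn_se = {
      chw <- layer$ch * h * w
      fl <- chw + (layer$ch + 1) * layer$rd + (layer$rd + 1) * layer$ch + chw
      row(name, n_params(layer), fl)
    },
    nn_eca = {
      chw <- layer$ch * h * w
      row(name, n_params(layer), chw + layer$k * layer$ch + chw)
    },
    nn_cbam = {
      chw <- layer$ch * h * w
      mlp <- 2 * ((layer$ch + 1) * layer$rd + (layer$rd + 1) * layer$ch)
      spk <- layer$spconv$k
      fl <- 2 * chw + mlp + chw +                       # channel branch
        2 * chw + h * w * (2 * spk^2 + 1) + chw         # spatial branch
      row(name, n_params(layer) + n_params(layer$spconv), fl)
    },
    nn_ca = {
      chw <- layer$ch * h * w
      fl <- 2 * chw + (h + w) * layer$ch * layer$mid +
        (h + w) * layer$mid * layer$ch + 2 * chw
      row(name, n_params(layer) + n_params(layer$bn), fl)
    },
    nn_lightcbam = {
      chw <- layer$ch * h * w
      spk <- layer$spconv$k
      fl <- chw + layer$k * layer$ch + chw +            # ECA branch
        2 * chw + h * w * (2 * spk^2 + 1) + chw +       # spatial branch
        3 * chw                                         # weighted mix
      row(name, n_params(layer) + n_params(layer$spconv), fl)
    },
    empty)
}

#' Per-layer complexity report
#'
#' Walks every layer of the model at the given input size and tabulates
#' trainable parameters and FLOPs per layer, plus totals in millions of
#' parameters and giga-FLOPs.
#'
#' @param m A `cow_model`.
#' @param input_size Input spatial size, default the model's configured one.
#' @param convention `"macs"` (default) or `"doubled"`; see the package
#'   vignette for the conventions.
#' @param include_head Include the final classifier layer (default `TRUE`).
#' @return List with `per_layer` (data frame), `total_params_M`,
#'   `total_flops_G`.
#' @export
complexity_report <- function(m, input_size = m$spec$input_size,
                              convention = c("macs", "doubled"),
                              include_head = TRUE) {
  convention <- match.arg(convention)
  res <- cx_rows(m$features, "features", input_size[1], input_size[2],
                 convention)
  rows <- res$rows
  if (include_head) {
    mult <- if (convention == "doubled") 2 else 1
    fc <- m$classifier
    rows <- rbind(rows, data.frame(layer = "fc", type = "nn_linear",
                                   params = n_params(fc),
                                   flops = mult * (fc$din + 1) * fc$dout))
  }
  rows$flops[is.na(rows$flops)] <- 0
  list(per_layer = rows,
       total_params_M = sum(rows$params) / 1e6,
       total_flops_G = sum(rows$flops) / 1e9)
}

#' Total trainable parameters in millions
#'
#' @param m A `cow_model`.
#' @param include_head Include the classifier head (default `TRUE`).
#' @return Parameter count divided by 1e6.
#' @export
count_params <- function(m, include_head = TRUE) {
  leaves <- nn_leaves(m$features)
  if (include_head) leaves <- c(leaves, nn_leaves(m$classifier))
  sum(vapply(leaves, n_params, 1)) / 1e6
}

#' Total forward-pass FLOPs in giga-operations
#'
#' @inheritParams complexity_report
#' @return Total FLOPs divided by 1e9.
#' @export
model_flops <- function(m, input_size = m$spec$input_size,
                        convention = c("macs", "doubled"),
                        include_head = TRUE) {
  complexity_report(m, input_size, convention, include_head)$total_flops_G
}
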