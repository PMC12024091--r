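# Training / evaluation pipeline: Adam with cosine-annealed learning rate,
# cross-entropy loss, on-the-fly augmentation, checkpointing, and Grad-CAM
# explanation panels.

#' Training configuration
#'
#' Defaults follow the study's optimizer settings: Adam, initial learning
#' rate 5e-4, weight decay 1e-4, batch size 32, cosine-annealing schedule.
#'
#' @param optimizer Only `"adam"` is implemented.
#' @param learning_rate Initial learning rate (> 0).
#' @param weight_decay L2 penalty coupled into the Adam update.
#' @param batch_size Mini-batch size (>= 1).
#' @param scheduler `"cosine"` (annealed to 0 over `max_epochs`) or
#'   `"constant"`.
#' @param max_epochs Training epochs.
#' @param seed Seed for shuffling, augmentation draws, and (when a spec is
#'   passed) weight initialization.
#' @param augment Apply training-time augmentation (default `TRUE`).
#' @param augment_cfg An [augment_config()] list.
#' @param patience Stop early after this many epochs without val top-1
#'   improvement (default `Inf`).
#' @param restore_best Restore the best-validation weights at the end
#'   (default `TRUE`); when `FALSE` the final-epoch weights are kept.
#' @return A `train_config` list.
#' @export
train_config <- function(optimizer = "adam", learning_rate = 5e-4,
                         weight_decay = 1e-4, batch_size = 32L,
                         scheduler = c("cosine", "constant"),
                         max_epochs = 100L, seed = 1L, augment = TRUE,
                         augment_cfg = augment_config(), patience = Inf,
                         restore_best = TRUE) {
  stopifnot(learning_rate >= 0, batch_size >= 1)
  optimizer <- match.arg(optimizer, "adam")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 scheduler = match.arg(scheduler),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), augment = augment,
                 augment_cfg = augment_cfg, patience = patience,
                 restore_best = restore_best),
            class = "train_config")
}

#' Stack samples into a network input batch
#'
#' @param samples List of `cow_sample`s with `(H, W, 3)` images in `[0, 1]`.
#' @return Array `(3, H, W, N)`.
#' @export
samples_to_batch <- function(samples) {
  stopifnot(length(samples) > 0)
  d <- dim(samples[[1]]$image)
  x <- array(0, c(3L, d[1], d[2], length(samples)))
  for (i in seq_along(samples)) x[, , , i] <- aperm(samples[[i]]$image, c(3, 1, 2))
  x
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# parameter/buffer snapshot for checkpointing and best-epoch restore
state_dict <- function(m) {
  lapply(nn_leaves(m$net), function(l) {
    s <- lapply(l$params, function(p) l[[p]])
    names(s) <- l$params
    if (!is.null(l$running_mean)) {
      s$running_mean <- l$running_mean
      s$running_var <- l$running_var
    }
    s
  })
}

load_state_dict <- function(m, sd) {
  leaves <- nn_leaves(m$net)
  stopifnot(length(leaves) == length(sd))
  for (i in seq_along(leaves)) {
    for (nm in names(sd[[i]])) leaves[[i]][[nm]] <- sd[[i]][[nm]]
  }
  invisible(m)
}

adam_step <- function(leaves, lr, wd, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (l in leaves) {
    for (p in l$params) {
      g <- l[[paste0("g_", p)]]
      if (is.null(g)) next
      if (wd > 0) g <- g + wd * l[[p]]
      if (is.null(l$opt)) l$opt <- list()
      st <- l$opt[[p]]
      if (is.null(st)) st <- list(m = 0, v = 0)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      l$opt[[p]] <- st
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      l[[p]] <- l[[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
}

epoch_lr <- function(cfg, epoch) {
  if (cfg$scheduler == "constant") return(cfg$learning_rate)
  0.5 * cfg$learning_rate * (1 + cos(pi * (epoch - 1) / cfg$max_epochs))
}

#' Train a model on a herd dataset
#'
#' Runs mini-batch Adam with cross-entropy loss, the configured on-the-fly
#' augmentations on the training split, a per-epoch validation pass, and
#' restores the best-validation weights at the end.  Fully reproducible
#' from the configuration seed.
#'
#' @param model A `cow_model`, or an `architecture_spec` (built with
#'   `cfg$seed`).
#' @param ds A `herd_dataset`.
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List: `model` (best-validation weights), `history` (data frame
#'   of epoch, lr, train_loss, val_top1), `best_epoch`, `best_val_top1`.
#' @export
train_model <- function(model, ds, cfg = train_config(), verbose = FALSE) {
  if (inherits(model, "architecture_spec")) model <- build_model(model, cfg$seed)
  stopifnot(inherits(model, "cow_model"))
  n_classes <- model$spec$num_classes
  if (length(ds$identities) != n_classes) {
    stop("model expects ", n_classes, " classes but dataset has ",
         length(ds$identities), call. = FALSE)
  }
  old_rng <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_rng)) assign(".Random.seed", old_rng,
                                        envir = globalenv()))
  set.seed(cfg$seed + 1L)
  leaves <- nn_leaves(model$net)
  train <- ds$train
  labels <- vapply(train, function(s) s$label_idx, 1L)
  ntr <- length(train)
  history <- NULL
  best <- list(top1 = -1, epoch = 0L, state = NULL)
  t_global <- 0L
  stale <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- epoch_lr(cfg, epoch)
    perm <- sample(ntr)
    losses <- c()
    for (start in seq(1, ntr, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, ntr)]
      batch <- train[idx]
      if (cfg$augment) {
        batch <- lapply(batch, function(s)
          augment(s, cfg$augment_cfg, seed = sample.int(2^30, 1)))
      }
      x <- normalize_input(model, samples_to_batch(batch))
      y <- labels[idx]
      ctx <- nn_ctx(training = TRUE)
      logits <- nn_forward(model$net, x, ctx)
      p <- softmax_cols(logits)
      loss <- -mean(log(pmax(p[cbind(y, seq_along(y))], 1e-12)))
      if (!is.finite(loss)) {
        stop("training diverged: non-finite loss at epoch ", epoch,
             call. = FALSE)
      }
      losses <- c(losses, loss)
      gy <- p
      gy[cbind(y, seq_along(y))] <- gy[cbind(y, seq_along(y))] - 1
      gy <- gy / length(y)
      nn_backward(model$net, gy, ctx)
      t_global <- t_global + 1L
      adam_step(leaves, lr, cfg$weight_decay, t_global)
    }
    val <- evaluate_model(model, ds$val)
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         train_loss = mean(losses),
                                         val_top1 = val$top1))
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  val top-1 %.3f",
                      epoch, lr, mean(losses), val$top1))
    }
    if (val$top1 > best$top1) {
      best <- list(top1 = val$top1, epoch = epoch, state = state_dict(model))
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$patience) break
    }
  }
  if (isTRUE(cfg$restore_best) && !is.null(best$state)) {
    load_state_dict(model, best$state)
  }
  list(model = model, history = history, best_epoch = best$epoch,
       best_val_top1 = best$top1)
}

#' Evaluate a model on a list of samples
#'
#' @param m A `cow_model`.
#' @param samples List of `cow_sample`s with `label_idx` set.
#' @param batch_size Forward batch size.
#' @return The [per_class_report()] list, plus `logits` and `labels`.
#' @export
evaluate_model <- function(m, samples, batch_size = 32L) {
  stopifnot(length(samples) > 0)
  labels <- vapply(samples, function(s) s$label_idx, 1L)
  logits <- NULL
  for (start in seq(1, length(samples), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(samples))
    logits <- rbind(logits, classify(m, samples_to_batch(samples[idx])))
  }
  rep <- per_class_report(logits, labels)
  rep$logits <- logits
  rep$labels <- labels
  rep
}

spec_digest <- function(spec) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(spec, f)
  unname(tools::md5sum(f))
}

#' Save a model checkpoint
#'
#' Stores the architecture spec, its digest, the seed, and all weights and
#' batch-norm statistics.
#'
#' @param m A `cow_model`.
#' @param path Output file.
#' @export
save_checkpoint <- function(m, path) {
  saveRDS(list(spec = m$spec, spec_md5 = spec_digest(m$spec), seed = m$seed,
               state = state_dict(m)), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return A `cow_model` with the stored weights.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$spec_md5, spec_digest(ck$spec))) {
    stop("checkpoint spec digest mismatch", call. = FALSE)
  }
  m <- build_model(ck$spec, ck$seed)
  load_state_dict(m, ck$state)
  m
}

# simple warm colormap for heatmap overlays (blue -> green -> red)
heat_colors <- function(v) {
  r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
  list(r = r, g = g, b = b)
}

#' Render a Grad-CAM overlay panel (original | overlay)
#'
#' @param image `(H, W, 3)` image in `[0, 1]`.
#' @param hm A `cow_heatmap` from [grad_cam()].
#' @param blend Overlay opacity (default 0.5).
#' @return `(H, 2W, 3)` panel array.
#' @export
heatmap_panel <- function(image, hm, blend = 0.5) {
  cols <- heat_colors(hm$values)
  over <- image
  over[, , 1] <- (1 - blend) * image[, , 1] + blend * cols$r
  over[, , 2] <- (1 - blend) * image[, , 2] + blend * cols$g
  over[, , 3] <- (1 - blend) * image[, , 3] + blend * cols$b
  d <- dim(image)
  panel <- array(0, c(d[1], 2 * d[2], 3))
  panel[, seq_len(d[2]), ] <- image
  panel[, d[2] + seq_len(d[2]), ] <- over
  panel
}

#' Grad-CAM explanation panels for original / rotated / occluded variants
#'
#' For each input sample, emits side-by-side (original | overlay) PNG
#' panels for the sample itself, a rotated copy, and an occluded copy,
#' localizing the evidence for the predicted identity.
#'
#' @param m A trained `cow_model`.
#' @param samples List of `cow_sample`s.
#' @param dir Output directory for PNG panels.
#' @param layer Grad-CAM target layer (default the deepest block).
#' @param seed Seed for the rotation/occlusion draws.
#' @return Data frame of written files and predicted classes, invisibly.
#' @export
explain_samples <- function(m, samples, dir,
                            layer = "features.stage6.block8", seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- NULL
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    variants <- list(
      original = s,
      rotated = augment(s, augment_config(p_hflip = 0, p_vflip = 0,
                                          noise_sd = 0, p_occlusion = 0),
                        seed = seed + i),
      occluded = augment(s, augment_config(p_hflip = 0, p_vflip = 0,
                                           noise_sd = 0, rotation_range = 0,
                                           p_occlusion = 1),
                         seed = seed + i))
    for (vn in names(variants)) {
      v <- variants[[vn]]
      logits <- classify(m, samples_to_batch(list(v)))
      pred <- which.max(logits[1, ])
      hm <- grad_cam(m, v$image, pred, layer)
      panel <- heatmap_panel(v$image, hm)
      fn <- file.path(dir, sprintf("sample%03d_%s.png", i, vn))
      png::writePNG(panel, fn)
      rows <- rbind(rows, data.frame(sample = i, variant = vn, file = fn,
                                     predicted = pred,
                                     degenerate = hm$degenerate))
    }
  }
  invisible(rows)
}
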