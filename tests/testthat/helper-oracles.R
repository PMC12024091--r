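# Scalar brute-force oracles, written with explicit loops and kept
# deliberately independent of the package's vectorized/Rcpp code paths.

oracle_gap <- function(f) {
  d <- dim(f)
  vapply(seq_len(d[1]), function(c) {
    s <- 0
    for (y in seq_len(d[2])) for (x in seq_len(d[3])) s <- s + f[c, y, x]
    s / (d[2] * d[3])
  }, 1)
}

# zero-padded 1-D convolution + sigmoid across the channel axis
oracle_eca <- function(f, k, w) {
  g <- oracle_gap(f)
  cc <- length(g)
  p <- (k - 1) / 2
  gp <- c(rep(0, p), g, rep(0, p))
  z <- numeric(cc)
  for (c in seq_len(cc)) {
    for (j in seq_len(k)) z[c] <- z[c] + w[j] * gp[c + j - 1]
  }
  1 / (1 + exp(-z))
}

# channel mean/max stack -> k x k same-padding conv -> sigmoid
oracle_spatial <- function(f, k, w, bias = 0) {
  d <- dim(f)
  avg <- matrix(0, d[2], d[3])
  mx <- matrix(-Inf, d[2], d[3])
  for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    for (c in seq_len(d[1])) {
      avg[y, x] <- avg[y, x] + f[c, y, x] / d[1]
      if (f[c, y, x] > mx[y, x]) mx[y, x] <- f[c, y, x]
    }
  }
  p <- (k - 1) / 2
  z <- matrix(bias, d[2], d[3])
  for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    for (ky in seq_len(k)) for (kx in seq_len(k)) {
      sy <- y + ky - 1 - p
      sx <- x + kx - 1 - p
      if (sy >= 1 && sy <= d[2] && sx >= 1 && sx <= d[3]) {
        z[y, x] <- z[y, x] + w[ky, kx, 1] * avg[sy, sx] +
          w[ky, kx, 2] * mx[sy, sx]
      }
    }
  }
  1 / (1 + exp(-z))
}

oracle_mul_channel <- function(f, w) {
  d <- dim(f)
  out <- f
  for (c in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    out[c, y, x] <- f[c, y, x] * w[c]
  }
  out
}

oracle_mul_spatial <- function(f, s) {
  d <- dim(f)
  out <- f
  for (c in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    out[c, y, x] <- f[c, y, x] * s[y, x]
  }
  out
}

# windowed SSIM with explicit loops (uniform reference implementation of the
# Gaussian-weighted statistics used by the package)
oracle_ssim_gray <- function(a, b, k, sigma) {
  g1 <- exp(-((seq_len(k) - (k + 1) / 2)^2) / (2 * sigma^2))
  kern <- outer(g1, g1)
  kern <- kern / sum(kern)
  h <- nrow(a); w <- ncol(a)
  c1 <- 0.01^2; c2 <- 0.03^2
  vals <- c()
  for (y in seq_len(h - k + 1)) for (x in seq_len(w - k + 1)) {
    wa <- a[y:(y + k - 1), x:(x + k - 1)]
    wb <- b[y:(y + k - 1), x:(x + k - 1)]
    mua <- sum(kern * wa); mub <- sum(kern * wb)
    va <- sum(kern * wa * wa) - mua^2
    vb <- sum(kern * wb * wb) - mub^2
    vab <- sum(kern * wa * wb) - mua * mub
    vals <- c(vals, ((2 * mua * mub + c1) * (2 * vab + c2)) /
                ((mua^2 + mub^2 + c1) * (va + vb + c2)))
  }
  mean(vals)
}

rand_fmap <- function(c, h, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(c * h * w), c(c, h, w))
}

# finite-difference gradient checker for engine layers
fd_gradcheck <- function(layer, x, eps = 1e-5, n_entries = 6, tol = 1e-4) {
  ctx <- nn_ctx(training = TRUE)
  y0 <- nn_forward(layer, x, ctx)
  wts <- array(stats::rnorm(length(y0)),
               if (is.null(dim(y0))) length(y0) else dim(y0))
  loss_of <- function(xx) {
    sum(nn_forward(layer, xx, nn_ctx(training = TRUE)) * wts)
  }
  nn_forward(layer, x, ctx)
  gx <- nn_backward(layer, wts, ctx)
  idx <- sample(length(x), min(n_entries, length(x)))
  num <- vapply(idx, function(i) {
    x2 <- x; x2[i] <- x2[i] + eps
    x3 <- x; x3[i] <- x3[i] - eps
    (loss_of(x2) - loss_of(x3)) / (2 * eps)
  }, 1)
  errs <- max(abs(num - gx[idx]) / pmax(1e-3, abs(num)))
  for (lf in cowbacknet:::nn_leaves(layer)) {
    for (p in lf$params) {
      nn_forward(layer, x, ctx)
      nn_backward(layer, wts, ctx)
      g <- lf[[paste0("g_", p)]]
      idx <- sample(length(lf[[p]]), min(n_entries, length(lf[[p]])))
      num <- vapply(idx, function(i) {
        v0 <- lf[[p]]
        lf[[p]][i] <- v0[i] + eps
        up <- loss_of(x)
        lf[[p]][i] <- v0[i] - eps
        dn <- loss_of(x)
        lf[[p]] <- v0
        (up - dn) / (2 * eps)
      }, 1)
      errs <- max(errs, max(abs(num - g[idx]) / pmax(1e-3, abs(num))))
    }
  }
  errs
}

# quick synthetic mini-dataset without the dedup pipeline, for pipeline tests
make_mini_dataset <- function(n_ids = 2, n_train = 8, n_eval = 3, size = 32,
                              seed = 99) {
  set.seed(seed)
  pats <- lapply(seq_len(n_ids), function(i) {
    generate_pattern(1000 + i, 10, 0.4, id = sprintf("cow%02d", i))
  })
  mk <- function(i, n, off) {
    lapply(seq_len(n), function(j) {
      s <- render_view(pats[[i]], "top", 1, seed = off + j, size = size)
      s$label_idx <- i
      s
    })
  }
  tr <- unlist(lapply(seq_len(n_ids), mk, n = n_train, off = 0),
               recursive = FALSE)
  va <- unlist(lapply(seq_len(n_ids), mk, n = n_eval, off = 500),
               recursive = FALSE)
  te <- unlist(lapply(seq_len(n_ids), mk, n = n_eval, off = 900),
               recursive = FALSE)
  structure(list(train = tr, val = va, test = te,
                 identities = vapply(pats, function(p) p$id, ""),
                 manifest = NULL, config = NULL),
            class = "herd_dataset")
}
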