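#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are stored as R arrays with dim (C, H, W, N), column-major,
// so the channel index varies fastest.  im2col rows are ordered
// (c fastest, then kh, then kw) to match a weight array of dim
// (C_in, K, K, C_out) flattened to a (C_in*K*K) x C_out matrix.

// [[Rcpp::export]]
NumericMatrix cb_im2col(NumericVector x, int C, int H, int W, int N,
                        int K, int stride, int pad) {
  const int OH = (H + 2 * pad - K) / stride + 1;
  const int OW = (W + 2 * pad - K) / stride + 1;
  NumericMatrix out(C * K * K, (R_xlen_t)OH * OW * N);
  const double* xp = x.begin();
  double* op = out.begin();
  const R_xlen_t collen = (R_xlen_t)C * K * K;
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        R_xlen_t col = oh + (R_xlen_t)OH * (ow + (R_xlen_t)OW * n);
        double* colp = op + col * collen;
        int iw0 = ow * stride - pad;
        int ih0 = oh * stride - pad;
        for (int kw = 0; kw < K; ++kw) {
          int iw = iw0 + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            int ih = ih0 + kh;
            if (ih < 0 || ih >= H) continue;
            const double* src =
              xp + (R_xlen_t)C * (ih + (R_xlen_t)H * (iw + (R_xlen_t)W * n));
            std::copy(src, src + C, colp + (R_xlen_t)C * (kh + K * kw));
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cb_col2im(NumericMatrix cols, int C, int H, int W, int N,
                        int K, int stride, int pad) {
  const int OH = (H + 2 * pad - K) / stride + 1;
  const int OW = (W + 2 * pad - K) / stride + 1;
  NumericVector x((R_xlen_t)C * H * W * N);
  double* xp = x.begin();
  const double* op = cols.begin();
  const R_xlen_t collen = (R_xlen_t)C * K * K;
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        R_xlen_t col = oh + (R_xlen_t)OH * (ow + (R_xlen_t)OW * n);
        const double* colp = op + col * collen;
        int iw0 = ow * stride - pad;
        int ih0 = oh * stride - pad;
        for (int kw = 0; kw < K; ++kw) {
          int iw = iw0 + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            int ih = ih0 + kh;
            if (ih < 0 || ih >= H) continue;
            double* dst =
              xp + (R_xlen_t)C * (ih + (R_xlen_t)H * (iw + (R_xlen_t)W * n));
            const double* src = colp + (R_xlen_t)C * (kh + K * kw);
            for (int c = 0; c < C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
  x.attr("dim") = IntegerVector::create(C, H, W, N);
  return x;
}

// Depthwise convolution, one K x K filter per channel, no bias.
// w has dim (K, K, C).
// [[Rcpp::export]]
NumericVector cb_dwconv_fwd(NumericVector x, int C, int H, int W, int N,
                            NumericVector w, int K, int stride, int pad) {
  const int OH = (H + 2 * pad - K) / stride + 1;
  const int OW = (W + 2 * pad - K) / stride + 1;
  NumericVector y((R_xlen_t)C * OH * OW * N);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        double* dst =
          yp + (R_xlen_t)C * (oh + (R_xlen_t)OH * (ow + (R_xlen_t)OW * n));
        int iw0 = ow * stride - pad;
        int ih0 = oh * stride - pad;
        for (int kw = 0; kw < K; ++kw) {
          int iw = iw0 + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            int ih = ih0 + kh;
            if (ih < 0 || ih >= H) continue;
            const double* src =
              xp + (R_xlen_t)C * (ih + (R_xlen_t)H * (iw + (R_xlen_t)W * n));
            const double* wk = wp + kh + K * kw;  // stride K*K over channels
            for (int c = 0; c < C; ++c) dst[c] += wk[(R_xlen_t)K * K * c] * src[c];
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(C, OH, OW, N);
  return y;
}

// [[Rcpp::export]]
NumericVector cb_dwconv_bwd_data(NumericVector gy, int C, int H, int W, int N,
                                 NumericVector w, int K, int stride, int pad) {
  const int OH = (H + 2 * pad - K) / stride + 1;
  const int OW = (W + 2 * pad - K) / stride + 1;
  NumericVector gx((R_xlen_t)C * H * W * N);
  const double* gp = gy.begin();
  const double* wp = w.begin();
  double* xp = gx.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const double* gsrc =
          gp + (R_xlen_t)C * (oh + (R_xlen_t)OH * (ow + (R_xlen_t)OW * n));
        int iw0 = ow * stride - pad;
        int ih0 = oh * stride - pad;
        for (int kw = 0; kw < K; ++kw) {
          int iw = iw0 + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            int ih = ih0 + kh;
            if (ih < 0 || ih >= H) continue;
            double* dst =
              xp + (R_xlen_t)C * (ih + (R_xlen_t)H * (iw + (R_xlen_t)W * n));
            const double* wk = wp + kh + K * kw;
            for (int c = 0; c < C; ++c) dst[c] += wk[(R_xlen_t)K * K * c] * gsrc[c];
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(C, H, W, N);
  return gx;
}

// [[Rcpp::export]]
NumericVector cb_dwconv_bwd_weight(NumericVector x, NumericVector gy,
                                   int C, int H, int W, int N,
                                   int K, int stride, int pad) {
  const int OH = (H + 2 * pad - K) / stride + 1;
  const int OW = (W + 2 * pad - K) / stride + 1;
  NumericVector gw((R_xlen_t)K * K * C);
  const double* xp = x.begin();
  const double* gp = gy.begin();
  double* wp = gw.begin();
  for (int n = 0; n < N; ++n) {
    for (int ow = 0; ow < OW; ++ow) {
      for (int oh = 0; oh < OH; ++oh) {
        const double* gsrc =
          gp + (R_xlen_t)C * (oh + (R_xlen_t)OH * (ow + (R_xlen_t)OW * n));
        int iw0 = ow * stride - pad;
        int ih0 = oh * stride - pad;
        for (int kw = 0; kw < K; ++kw) {
          int iw = iw0 + kw;
          if (iw < 0 || iw >= W) continue;
          for (int kh = 0; kh < K; ++kh) {
            int ih = ih0 + kh;
            if (ih < 0 || ih >= H) continue;
            const double* src =
              xp + (R_xlen_t)C * (ih + (R_xlen_t)H * (iw + (R_xlen_t)W * n));
            double* wk = wp + kh + K * kw;
            for (int c = 0; c < C; ++c) wk[(R_xlen_t)K * K * c] += src[c] * gsrc[c];
          }
        }
      }
    }
  }
  gw.attr("dim") = IntegerVector::create(K, K, C);
  return gw;
}

// Per-row max and (1-based) argmax of a matrix; ties go to the lowest index.
// [[Rcpp::export]]
List cb_rowmax(NumericMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericVector mx(nr);
  IntegerVector idx(nr);
  for (int i = 0; i < nr; ++i) {
    double best = m(i, 0);
    int bj = 0;
    for (int j = 1; j < nc; ++j) {
      if (m(i, j) > best) { best = m(i, j); bj = j; }
    }
    mx[i] = best;
    idx[i] = bj + 1;
  }
  return List::create(_["max"] = mx, _["idx"] = idx);
}

// Per-column max and (1-based row) argmax; ties go to the lowest index.
// [[Rcpp::export]]
List cb_colmax(NumericMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericVector mx(nc);
  IntegerVector idx(nc);
  for (int j = 0; j < nc; ++j) {
    double best = m(0, j);
    int bi = 0;
    for (int i = 1; i < nr; ++i) {
      if (m(i, j) > best) { best = m(i, j); bi = i; }
    }
    mx[j] = best;
    idx[j] = bi + 1;
  }
  return List::create(_["max"] = mx, _["idx"] = idx);
}

// ---- broadcast / pooling kernels (hot paths inside attention blocks) ----

// per-(channel,sample) spatial mean of x (C,H,W,N) -> (C,N)
// [[Rcpp::export]]
NumericMatrix cb_gap2d(NumericVector x, int C, int H, int W, int N) {
  NumericMatrix g(C, N);
  const double* xp = x.begin();
  const R_xlen_t plane = (R_xlen_t)C * H * W;
  for (int n = 0; n < N; ++n) {
    const double* base = xp + plane * n;
    double* gp = &g(0, n);
    for (R_xlen_t i = 0; i < plane; ++i) gp[i % C] += base[i];
  }
  const double inv = 1.0 / ((double)H * W);
  for (R_xlen_t i = 0; i < (R_xlen_t)C * N; ++i) g[i] *= inv;
  return g;
}

// expand g (C,N) over H x W -> (C,H,W,N)
// [[Rcpp::export]]
NumericVector cb_gap_expand(NumericMatrix g, int H, int W) {
  const int C = g.nrow(), N = g.ncol();
  NumericVector y((R_xlen_t)C * H * W * N);
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    const double* gp = &g(0, n);
    for (int hw = 0; hw < H * W; ++hw) {
      double* dst = yp + (R_xlen_t)C * (hw + (R_xlen_t)H * W * n);
      std::copy(gp, gp + C, dst);
    }
  }
  y.attr("dim") = IntegerVector::create(C, H, W, N);
  return y;
}

// x (C,H,W,N) * s (C,N), broadcast over space
// [[Rcpp::export]]
NumericVector cb_cmul(NumericVector x, NumericMatrix s,
                      int C, int H, int W, int N) {
  NumericVector y(clone(x));
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    const double* sp = &s(0, n);
    for (int hw = 0; hw < H * W; ++hw) {
      double* dst = yp + (R_xlen_t)C * (hw + (R_xlen_t)H * W * n);
      for (int c = 0; c < C; ++c) dst[c] *= sp[c];
    }
  }
  y.attr("dim") = IntegerVector::create(C, H, W, N);
  return y;
}

// sum over space of gy * x -> (C,N)
// [[Rcpp::export]]
NumericMatrix cb_cmul_sum(NumericVector gy, NumericVector x,
                          int C, int H, int W, int N) {
  NumericMatrix out(C, N);
  const double* gp = gy.begin();
  const double* xp = x.begin();
  const R_xlen_t plane = (R_xlen_t)C * H * W;
  for (int n = 0; n < N; ++n) {
    double* op = &out(0, n);
    const double* g0 = gp + plane * n;
    const double* x0 = xp + plane * n;
    for (R_xlen_t i = 0; i < plane; ++i) op[i % C] += g0[i] * x0[i];
  }
  return out;
}

// x (C,H,W,N) * s (H,W,N), broadcast over channels
// [[Rcpp::export]]
NumericVector cb_smul(NumericVector x, NumericVector s,
                      int C, int H, int W, int N) {
  NumericVector y(clone(x));
  double* yp = y.begin();
  const double* sp = s.begin();
  const R_xlen_t m = (R_xlen_t)H * W * N;
  for (R_xlen_t i = 0; i < m; ++i) {
    double* dst = yp + (R_xlen_t)C * i;
    const double v = sp[i];
    for (int c = 0; c < C; ++c) dst[c] *= v;
  }
  y.attr("dim") = IntegerVector::create(C, H, W, N);
  return y;
}

// sum over channels of gy * x -> (H,W,N)
// [[Rcpp::export]]
NumericVector cb_smul_sum(NumericVector gy, NumericVector x,
                          int C, int H, int W, int N) {
  const R_xlen_t m = (R_xlen_t)H * W * N;
  NumericVector out(m);
  const double* gp = gy.begin();
  const double* xp = x.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < m; ++i) {
    const double* g0 = gp + (R_xlen_t)C * i;
    const double* x0 = xp + (R_xlen_t)C * i;
    double acc = 0;
    for (int c = 0; c < C; ++c) acc += g0[c] * x0[c];
    op[i] = acc;
  }
  out.attr("dim") = IntegerVector::create(H, W, N);
  return out;
}

// channel-wise mean and max stack (2,H,W,N) plus 1-based argmax channel
// [[Rcpp::export]]
List cb_meanmax(NumericVector x, int C, int H, int W, int N) {
  const R_xlen_t m = (R_xlen_t)H * W * N;
  NumericVector stack(2 * m);
  IntegerVector idx(m);
  const double* xp = x.begin();
  double* sp = stack.begin();
  for (R_xlen_t i = 0; i < m; ++i) {
    const double* x0 = xp + (R_xlen_t)C * i;
    double acc = x0[0], best = x0[0];
    int bi = 0;
    for (int c = 1; c < C; ++c) {
      acc += x0[c];
      if (x0[c] > best) { best = x0[c]; bi = c; }
    }
    sp[2 * i] = acc / C;
    sp[2 * i + 1] = best;
    idx[i] = bi + 1;
  }
  stack.attr("dim") = IntegerVector::create(2, H, W, N);
  return List::create(_["stack"] = stack, _["idx"] = idx);
}

// distribute mean/max-stack gradients back over channels
// [[Rcpp::export]]
NumericVector cb_meanmax_bwd(NumericVector gstack, IntegerVector idx,
                             int C, int H, int W, int N) {
  const R_xlen_t m = (R_xlen_t)H * W * N;
  NumericVector gx((R_xlen_t)C * m);
  const double* gp = gstack.begin();
  double* xp = gx.begin();
  for (R_xlen_t i = 0; i < m; ++i) {
    double* dst = xp + (R_xlen_t)C * i;
    const double gm = gp[2 * i] / C;
    for (int c = 0; c < C; ++c) dst[c] = gm;
    dst[idx[i] - 1] += gp[2 * i + 1];
  }
  gx.attr("dim") = IntegerVector::create(C, H, W, N);
  return gx;
}

// fused per-channel affine: y[c, i] = a[c] * x[c, i] + b[c]
// [[Rcpp::export]]
NumericVector cb_chan_affine(NumericVector x, NumericVector a,
                             NumericVector b, int C) {
  const R_xlen_t m = x.size() / C;
  NumericVector y(x.size());
  const double* xp = x.begin();
  const double* ap = a.begin();
  const double* bp = b.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < m; ++i) {
    const double* x0 = xp + (R_xlen_t)C * i;
    double* y0 = yp + (R_xlen_t)C * i;
    for (int c = 0; c < C; ++c) y0[c] = ap[c] * x0[c] + bp[c];
  }
  y.attr("dim") = x.attr("dim");
  return y;
}

// swish forward: y = x * sigmoid(x); returns y and the sigmoid
// [[Rcpp::export]]
List cb_swish_fwd(NumericVector x) {
  NumericVector y(x.size()), s(x.size());
  const double* xp = x.begin();
  double* yp = y.begin();
  double* sp = s.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double sig = 1.0 / (1.0 + std::exp(-xp[i]));
    sp[i] = sig;
    yp[i] = xp[i] * sig;
  }
  y.attr("dim") = x.attr("dim");
  return List::create(_["y"] = y, _["s"] = s);
}

// swish backward: gy * s * (1 + x * (1 - s))
// [[Rcpp::export]]
NumericVector cb_swish_bwd(NumericVector gy, NumericVector x,
                           NumericVector s) {
  NumericVector gx(gy.size());
  const double* gp = gy.begin();
  const double* xp = x.begin();
  const double* sp = s.begin();
  double* op = gx.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) {
    op[i] = gp[i] * sp[i] * (1.0 + xp[i] * (1.0 - sp[i]));
  }
  gx.attr("dim") = gy.attr("dim");
  return gx;
}
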