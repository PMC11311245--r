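#include <Rcpp.h>
using namespace Rcpp;

// Channels-first im2col: activations are [C, H, W, N] column-major (C
// fastest).  Output matrix has C*kh*kw rows (c fastest, then kernel row,
// then kernel column) and outH*outW*N columns (output row fastest).
// [[Rcpp::export]]
NumericMatrix im2col_cf(const NumericVector& x, int C, int H, int W, int N,
                        int kh, int kw, int sh, int sw) {
  const int outH = (H - kh) / sh + 1;
  const int outW = (W - kw) / sw + 1;
  const int R = C * kh * kw;
  const R_xlen_t P = (R_xlen_t)outH * outW * N;
  NumericMatrix out(R, P);
  const double* px = REAL(x);
  double* po = REAL(out);
  for (int n = 0; n < N; ++n)
    for (int ow = 0; ow < outW; ++ow)
      for (int oh = 0; oh < outH; ++oh) {
        R_xlen_t col = oh + (R_xlen_t)outH * (ow + (R_xlen_t)outW * n);
        double* dst = po + col * R;
        for (int j = 0; j < kw; ++j) {
          const int w = ow * sw + j;
          for (int i = 0; i < kh; ++i) {
            const int h = oh * sh + i;
            const double* src = px + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
            std::copy(src, src + C, dst + (R_xlen_t)C * (i + kh * j));
          }
        }
      }
  return out;
}

// Adjoint of im2col_cf: scatter-add columns back into an activation array.
// [[Rcpp::export]]
NumericVector col2im_cf(const NumericMatrix& cols, int C, int H, int W, int N,
                        int kh, int kw, int sh, int sw) {
  const int outH = (H - kh) / sh + 1;
  const int outW = (W - kw) / sw + 1;
  const int R = C * kh * kw;
  NumericVector x((R_xlen_t)C * H * W * N);
  const double* pc = REAL(cols);
  double* px = REAL(x);
  for (int n = 0; n < N; ++n)
    for (int ow = 0; ow < outW; ++ow)
      for (int oh = 0; oh < outH; ++oh) {
        R_xlen_t col = oh + (R_xlen_t)outH * (ow + (R_xlen_t)outW * n);
        const double* src = pc + col * R;
        for (int j = 0; j < kw; ++j) {
          const int w = ow * sw + j;
          for (int i = 0; i < kh; ++i) {
            const int h = oh * sh + i;
            double* dst = px + (R_xlen_t)C * (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
            const double* s = src + (R_xlen_t)C * (i + kh * j);
            for (int c = 0; c < C; ++c) dst[c] += s[c];
          }
        }
      }
  return x;
}

// Fused batch-norm + ReLU forward over [C, M] (C fastest).  If use_given,
// normalizes with the supplied statistics; otherwise computes batch
// statistics.  Returns the activated output plus the statistics needed for
// the backward pass.
// [[Rcpp::export]]
List bn_relu_fwd(const NumericVector& x, int C, const NumericVector& gamma,
                 const NumericVector& beta, const NumericVector& mu_in,
                 const NumericVector& va_in, bool use_given) {
  const R_xlen_t M = x.size() / C;
  NumericVector mu(C), va(C);
  if (use_given) {
    mu = clone(mu_in); va = clone(va_in);
  } else {
    std::vector<double> s(C, 0.0), s2(C, 0.0);
    const double* px = REAL(x);
    for (R_xlen_t m = 0; m < M; ++m) {
      const double* col = px + m * C;
      for (int c = 0; c < C; ++c) { s[c] += col[c]; s2[c] += col[c] * col[c]; }
    }
    for (int c = 0; c < C; ++c) {
      mu[c] = s[c] / M;
      va[c] = s2[c] / M - mu[c] * mu[c];
    }
  }
  NumericVector inv(C);
  for (int c = 0; c < C; ++c) inv[c] = 1.0 / std::sqrt(va[c] + 1e-5);
  NumericVector y(x.size());
  const double* px = REAL(x);
  double* py = REAL(y);
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* xc = px + m * C;
    double* yc = py + m * C;
    for (int c = 0; c < C; ++c) {
      double v = (xc[c] - mu[c]) * inv[c] * gamma[c] + beta[c];
      yc[c] = v > 0 ? v : 0.0;
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["va"] = va, _["inv"] = inv);
}

// Fused batch-norm + ReLU backward.  `fixed` means the normalization
// statistics were constants (frozen or stored), not batch functions.
// [[Rcpp::export]]
List bn_relu_bwd(const NumericVector& g, const NumericVector& x,
                 const NumericVector& y, const NumericVector& mu,
                 const NumericVector& inv, const NumericVector& gamma,
                 int C, bool fixed) {
  const R_xlen_t M = g.size() / C;
  std::vector<double> dg(C, 0.0), db(C, 0.0);
  const double* pg = REAL(g);
  const double* px = REAL(x);
  const double* pyv = REAL(y);
  for (R_xlen_t m = 0; m < M; ++m) {
    const double* gc = pg + m * C;
    const double* xc = px + m * C;
    const double* yc = pyv + m * C;
    for (int c = 0; c < C; ++c)
      if (yc[c] > 0) {
        dg[c] += gc[c] * (xc[c] - mu[c]) * inv[c];
        db[c] += gc[c];
      }
  }
  NumericVector gx(g.size());
  double* pgx = REAL(gx);
  if (fixed) {
    for (R_xlen_t m = 0; m < M; ++m) {
      const double* gc = pg + m * C;
      const double* yc = pyv + m * C;
      double* oc = pgx + m * C;
      for (int c = 0; c < C; ++c)
        oc[c] = yc[c] > 0 ? gc[c] * gamma[c] * inv[c] : 0.0;
    }
  } else {
    for (R_xlen_t m = 0; m < M; ++m) {
      const double* gc = pg + m * C;
      const double* xc = px + m * C;
      const double* yc = pyv + m * C;
      double* oc = pgx + m * C;
      for (int c = 0; c < C; ++c)
        if (yc[c] > 0) {
          double xh = (xc[c] - mu[c]) * inv[c];
          oc[c] = inv[c] * gamma[c] * (gc[c] - db[c] / M - xh * dg[c] / M);
        } else oc[c] = 0.0;
    }
  }
  return List::create(_["gx"] = gx,
                      _["dgamma"] = NumericVector(dg.begin(), dg.end()),
                      _["dbeta"] = NumericVector(db.begin(), db.end()));
}

// Direct strided convolution forward: x [C,H,W,N] -> y [K,outH,outW,N],
// weights [C,kh,kw,K], bias [K].  Avoids materializing the im2col matrix;
// equivalent to crossprod(weight matrix, im2col_cf(x, ...)).
// [[Rcpp::export]]
NumericVector conv_fwd(const NumericVector& x, const NumericVector& w,
                       const NumericVector& b, int C, int H, int W, int N,
                       int kh, int kw, int sh, int sw, int K) {
  const int outH = (H - kh) / sh + 1;
  const int outW = (W - kw) / sw + 1;
  NumericVector y((R_xlen_t)K * outH * outW * N);
  const double* px = REAL(x);
  const double* pw = REAL(w);
  const double* pb = REAL(b);
  double* py = REAL(y);
  const R_xlen_t kstride = (R_xlen_t)C * kh * kw;
  std::vector<double> acc(K);
  for (int n = 0; n < N; ++n)
    for (int ow = 0; ow < outW; ++ow)
      for (int oh = 0; oh < outH; ++oh) {
        for (int k = 0; k < K; ++k) acc[k] = pb[k];
        for (int j = 0; j < kw; ++j) {
          const int wcol = ow * sw + j;
          for (int i = 0; i < kh; ++i) {
            const int h = oh * sh + i;
            const double* xp = px + (R_xlen_t)C * (h + (R_xlen_t)H * (wcol + (R_xlen_t)W * n));
            const double* wp = pw + (R_xlen_t)C * (i + (R_xlen_t)kh * j);
            for (int k = 0; k < K; ++k) {
              const double* wk = wp + k * kstride;
              double s = 0.0;
              for (int c = 0; c < C; ++c) s += xp[c] * wk[c];
              acc[k] += s;
            }
          }
        }
        double* yp = py + (R_xlen_t)K * (oh + (R_xlen_t)outH * (ow + (R_xlen_t)outW * n));
        for (int k = 0; k < K; ++k) yp[k] = acc[k];
      }
  return y;
}

// Direct convolution backward: returns gradients w.r.t. input, weights and
// bias given upstream gradient g [K,outH,outW,N].
// [[Rcpp::export]]
List conv_bwd(const NumericVector& g, const NumericVector& x,
              const NumericVector& w, int C, int H, int W, int N,
              int kh, int kw, int sh, int sw, int K) {
  const int outH = (H - kh) / sh + 1;
  const int outW = (W - kw) / sw + 1;
  NumericVector dx((R_xlen_t)C * H * W * N);
  NumericVector dw(w.size());
  NumericVector db(K);
  const double* pg = REAL(g);
  const double* px = REAL(x);
  const double* pw = REAL(w);
  double* pdx = REAL(dx);
  double* pdw = REAL(dw);
  double* pdb = REAL(db);
  const R_xlen_t kstride = (R_xlen_t)C * kh * kw;
  for (int n = 0; n < N; ++n)
    for (int ow = 0; ow < outW; ++ow)
      for (int oh = 0; oh < outH; ++oh) {
        const double* gp = pg + (R_xlen_t)K * (oh + (R_xlen_t)outH * (ow + (R_xlen_t)outW * n));
        for (int k = 0; k < K; ++k) pdb[k] += gp[k];
        for (int j = 0; j < kw; ++j) {
          const int wcol = ow * sw + j;
          for (int i = 0; i < kh; ++i) {
            const int h = oh * sh + i;
            const R_xlen_t xoff = (R_xlen_t)C * (h + (R_xlen_t)H * (wcol + (R_xlen_t)W * n));
            const double* xp = px + xoff;
            double* dxp = pdx + xoff;
            const double* wp = pw + (R_xlen_t)C * (i + (R_xlen_t)kh * j);
            double* dwp = pdw + (R_xlen_t)C * (i + (R_xlen_t)kh * j);
            for (int k = 0; k < K; ++k) {
              const double gk = gp[k];
              if (gk == 0.0) continue;
              const double* wk = wp + k * kstride;
              double* dwk = dwp + k * kstride;
              for (int c = 0; c < C; ++c) {
                dxp[c] += wk[c] * gk;
                dwk[c] += xp[c] * gk;
              }
            }
          }
        }
      }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Polyphase rational resampler for all columns of a matrix: output row k
// (0-based) is sum_l h[p + up*l] * x[(q - p)/up - l, ] with q = m + k*down,
// p = q mod up, m the FIR group delay.  Equivalent to zero-stuffing by
// `up`, filtering with `h`, group-delay compensation and decimation by
// `down`.
// [[Rcpp::export]]
NumericMatrix polyphase_resample(const NumericMatrix& x, const NumericVector& h,
                                 int up, int down, int n_out) {
  const int n = x.nrow(), ncol = x.ncol(), taps = h.size();
  const int m = (taps - 1) / 2;
  NumericMatrix y(n_out, ncol);
  const double* px = REAL(x);
  double* py = REAL(y);
  for (int k = 0; k < n_out; ++k) {
    const long q = (long)m + (long)k * down;
    const int p = (int)(q % up);
    const long s0 = (q - p) / up;
    for (int l = 0, j = p; j < taps; ++l, j += up) {
      const long src = s0 - l;
      if (src < 0 || src >= n) continue;
      const double c = h[j];
      const double* xr = px + src;
      double* yr = py + k;
      for (int col = 0; col < ncol; ++col)
        yr[(size_t)col * n_out] += c * xr[(size_t)col * n];
    }
  }
  return y;
}
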