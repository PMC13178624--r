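// Hot inner kernels of the PVNet layers: depthwise 3x3 convolution,
// im2col/col2im for full 3x3 convolutions, and exact GELU. Feature maps are
// column-major [H, W, N, C] arrays; weight-row ordering of the 3x3 offsets
// is o = di + 3*dj (di = row offset, dj = column offset), matching the R
// initializers.

#include <Rcpp.h>
using namespace Rcpp;

static inline int idx4(int h, int w, int n, int c, int H, int W, int N) {
  return h + H * (w + W * (n + (R_xlen_t)N * c));
}

// [[Rcpp::export]]
NumericVector dw3_forward(const NumericVector& x, const IntegerVector& dims,
                          const NumericMatrix& Wt, const NumericVector& b) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  NumericVector y(x.size());
  for (int c = 0; c < C; ++c) {
    double w9[9];
    for (int o = 0; o < 9; ++o) w9[o] = Wt(o, c);
    const double bc = b[c];
    for (int n = 0; n < N; ++n) {
      const double* xs = &x[idx4(0, 0, n, c, H, W, N)];
      double* ys = &y[idx4(0, 0, n, c, H, W, N)];
      for (int w = 0; w < W; ++w) {
        const bool wl = (w > 0), wr = (w < W - 1);
        const double* c0 = xs + H * (w - 1);
        const double* c1 = xs + H * w;
        const double* c2 = xs + H * (w + 1);
        double* yc = ys + H * w;
        for (int h = 0; h < H; ++h) {
          const bool ht = (h > 0), hb = (h < H - 1);
          double acc = bc + c1[h] * w9[4];
          if (ht) acc += c1[h - 1] * w9[3];
          if (hb) acc += c1[h + 1] * w9[5];
          if (wl) {
            acc += c0[h] * w9[1];
            if (ht) acc += c0[h - 1] * w9[0];
            if (hb) acc += c0[h + 1] * w9[2];
          }
          if (wr) {
            acc += c2[h] * w9[7];
            if (ht) acc += c2[h - 1] * w9[6];
            if (hb) acc += c2[h + 1] * w9[8];
          }
          yc[h] = acc;
        }
      }
    }
  }
  y.attr("dim") = dims;
  return y;
}

// [[Rcpp::export]]
List dw3_backward(const NumericVector& x, const IntegerVector& dims,
                  const NumericMatrix& Wt, const NumericVector& dy) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  NumericVector dx(x.size());
  NumericMatrix dW(9, C);
  NumericVector db(C);
  // dx is a correlation with the flipped kernel; dW accumulates x against
  // dy per offset. Both are done column-slice-wise to stay branch-light.
  for (int c = 0; c < C; ++c) {
    double w9[9], dw9[9] = {0};
    for (int o = 0; o < 9; ++o) w9[o] = Wt(o, c);
    double dbc = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xs = &x[idx4(0, 0, n, c, H, W, N)];
      const double* dys = &dy[idx4(0, 0, n, c, H, W, N)];
      double* dxs = &dx[idx4(0, 0, n, c, H, W, N)];
      for (int w = 0; w < W; ++w) {
        const bool wl = (w > 0), wr = (w < W - 1);
        const double* x0 = xs + H * (w - 1);
        const double* x1 = xs + H * w;
        const double* x2 = xs + H * (w + 1);
        double* d0 = dxs + H * (w - 1);
        double* d1 = dxs + H * w;
        double* d2 = dxs + H * (w + 1);
        const double* g = dys + H * w;
        for (int h = 0; h < H; ++h) {
          const bool ht = (h > 0), hb = (h < H - 1);
          const double gv = g[h];
          dbc += gv;
          dw9[4] += gv * x1[h];
          d1[h] += gv * w9[4];
          if (ht) { dw9[3] += gv * x1[h - 1]; d1[h - 1] += gv * w9[3]; }
          if (hb) { dw9[5] += gv * x1[h + 1]; d1[h + 1] += gv * w9[5]; }
          if (wl) {
            dw9[1] += gv * x0[h]; d0[h] += gv * w9[1];
            if (ht) { dw9[0] += gv * x0[h - 1]; d0[h - 1] += gv * w9[0]; }
            if (hb) { dw9[2] += gv * x0[h + 1]; d0[h + 1] += gv * w9[2]; }
          }
          if (wr) {
            dw9[7] += gv * x2[h]; d2[h] += gv * w9[7];
            if (ht) { dw9[6] += gv * x2[h - 1]; d2[h - 1] += gv * w9[6]; }
            if (hb) { dw9[8] += gv * x2[h + 1]; d2[h + 1] += gv * w9[8]; }
          }
        }
      }
    }
    for (int o = 0; o < 9; ++o) dW(o, c) = dw9[o];
    db[c] = dbc;
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// y = a[c] * x + b[c], channels as trailing dimension blocks.
// [[Rcpp::export]]
NumericVector channel_affine(const NumericVector& x, const int C,
                             const NumericVector& a, const NumericVector& b) {
  NumericVector y(x.size());
  const R_xlen_t M = x.size() / C;
  for (int c = 0; c < C; ++c) {
    const double ac = a[c], bc = b[c];
    const double* xs = &x[(R_xlen_t)c * M];
    double* ys = &y[(R_xlen_t)c * M];
    for (R_xlen_t i = 0; i < M; ++i) ys[i] = ac * xs[i] + bc;
  }
  SEXP d = x.attr("dim");
  if (!Rf_isNull(d)) y.attr("dim") = d;
  return y;
}

// dx = inv[c] * (dxh - m1[c] - xhat * m2[c]): batch-norm input gradient.
// [[Rcpp::export]]
NumericVector bn_backward_core(const NumericVector& dxh,
                               const NumericVector& xhat, const int C,
                               const NumericVector& inv,
                               const NumericVector& m1,
                               const NumericVector& m2) {
  NumericVector dx(dxh.size());
  const R_xlen_t M = dxh.size() / C;
  for (int c = 0; c < C; ++c) {
    const double ic = inv[c], m1c = m1[c], m2c = m2[c];
    const double* g = &dxh[(R_xlen_t)c * M];
    const double* xh = &xhat[(R_xlen_t)c * M];
    double* d = &dx[(R_xlen_t)c * M];
    for (R_xlen_t i = 0; i < M; ++i) d[i] = ic * (g[i] - m1c - xh[i] * m2c);
  }
  return dx;
}

// [[Rcpp::export]]
NumericMatrix im2col3(const NumericVector& x, const IntegerVector& dims,
                      const int stride) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int Ho = (H - 1) / stride + 1, Wo = (W - 1) / stride + 1;
  const R_xlen_t rows = (R_xlen_t)Ho * Wo * N;
  NumericMatrix cols(rows, 9 * C);
  for (int dj = 0; dj < 3; ++dj) {
    for (int di = 0; di < 3; ++di) {
      const int o = (dj * 3 + di);  // column-block index, (dj outer, di inner)
      for (int c = 0; c < C; ++c) {
        double* dst = &cols(0, o * C + c);
        for (int n = 0; n < N; ++n) {
          const double* xs = &x[idx4(0, 0, n, c, H, W, N)];
          for (int wo = 0; wo < Wo; ++wo) {
            const int wj = wo * stride + dj - 1;
            double* d = dst + (R_xlen_t)(n * Wo + wo) * Ho;
            if (wj < 0 || wj >= W) {
              for (int ho = 0; ho < Ho; ++ho) d[ho] = 0.0;
              continue;
            }
            const double* col = xs + H * wj;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + di - 1;
              d[ho] = (hi < 0 || hi >= H) ? 0.0 : col[hi];
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im3(const NumericMatrix& dcols, const IntegerVector& dims,
                      const int stride) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int Ho = (H - 1) / stride + 1, Wo = (W - 1) / stride + 1;
  NumericVector dx((R_xlen_t)H * W * N * C);
  for (int dj = 0; dj < 3; ++dj) {
    for (int di = 0; di < 3; ++di) {
      const int o = (dj * 3 + di);
      for (int c = 0; c < C; ++c) {
        const double* src = &dcols(0, o * C + c);
        for (int n = 0; n < N; ++n) {
          double* xs = &dx[idx4(0, 0, n, c, H, W, N)];
          for (int wo = 0; wo < Wo; ++wo) {
            const int wj = wo * stride + dj - 1;
            if (wj < 0 || wj >= W) continue;
            const double* s = src + (R_xlen_t)(n * Wo + wo) * Ho;
            double* col = xs + H * wj;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride + di - 1;
              if (hi >= 0 && hi < H) col[hi] += s[ho];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = dims;
  return dx;
}

// GELU in its tanh approximation (the form standard in transformer
// implementations): 0.5 x (1 + tanh(sqrt(2/pi) (x + 0.044715 x^3))).
static const double kG = 0.7978845608028654;   // sqrt(2/pi)
static const double kG3 = 0.044715;

// [[Rcpp::export]]
NumericVector gelu_forward_cpp(const NumericVector& x) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double v = x[i];
    y[i] = 0.5 * v * (1.0 + tanh(kG * (v + kG3 * v * v * v)));
  }
  SEXP d = x.attr("dim");
  if (!Rf_isNull(d)) y.attr("dim") = d;
  return y;
}

// [[Rcpp::export]]
NumericVector gelu_backward_cpp(const NumericVector& x,
                                const NumericVector& dy) {
  NumericVector dx(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double v = x[i];
    const double t = tanh(kG * (v + kG3 * v * v * v));
    const double du = kG * (1.0 + 3.0 * kG3 * v * v);
    dx[i] = dy[i] * (0.5 * (1.0 + t) + 0.5 * v * (1.0 - t * t) * du);
  }
  SEXP d = x.attr("dim");
  if (!Rf_isNull(d)) dx.attr("dim") = d;
  return dx;
}

// Rotate adjacent column pairs of token matrix x (rows = tokens) by the
// per-row, per-pair angles whose cos/sin are given. Used for RoPE.
// [[Rcpp::export]]
NumericMatrix rope_apply_cpp(const NumericMatrix& x, const NumericMatrix& co,
                             const NumericMatrix& si) {
  const int n = x.nrow(), D = x.ncol();
  NumericMatrix y(n, D);
  for (int p = 0; p < D / 2; ++p) {
    const double* x1 = &x(0, 2 * p);
    const double* x2 = &x(0, 2 * p + 1);
    const double* cp = &co(0, p);
    const double* sp = &si(0, p);
    double* y1 = &y(0, 2 * p);
    double* y2 = &y(0, 2 * p + 1);
    for (int i = 0; i < n; ++i) {
      y1[i] = x1[i] * cp[i] - x2[i] * sp[i];
      y2[i] = x1[i] * sp[i] + x2[i] * cp[i];
    }
  }
  return y;
}
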