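#include <Rcpp.h>
using namespace Rcpp;

// Tensors are column-major numeric vectors with layout [C, H, W, N]
// (channel fastest). im2col emits a [C*k*k, outH*outW*N] matrix whose
// column order matches the output tensor layout [outH fastest, then outW,
// then N], so conv forward is a single GEMM:
//   Y[Cout, L] = W[Cout, C*k*k] %*% cols.
// Within a column the row order is (c, kh, kw) with c fastest, matching a
// weight matrix stored as [Cout, C*k*k] with column index c + C*(kh + k*kw).

// [[Rcpp::export]]
NumericMatrix im2col_nchw(NumericVector x, int C, int H, int W, int N,
                          int k, int stride, int pad) {
  const int outH = (H + 2 * pad - k) / stride + 1;
  const int outW = (W + 2 * pad - k) / stride + 1;
  const int rows = C * k * k;
  const int L = outH * outW * N;
  NumericMatrix cols(rows, L);
  const double *xp = x.begin();
  double *cp = cols.begin();
  for (int n = 0; n < N; ++n) {
    const double *xn = xp + (R_xlen_t)n * C * H * W;
    for (int wo = 0; wo < outW; ++wo) {
      for (int ho = 0; ho < outH; ++ho) {
        const R_xlen_t col = (R_xlen_t)n * outH * outW + (R_xlen_t)wo * outH + ho;
        double *dst = cp + col * rows;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int kw = 0; kw < k; ++kw) {
          const int w = w0 + kw;
          for (int kh = 0; kh < k; ++kh) {
            const int h = h0 + kh;
            double *d = dst + (R_xlen_t)C * (kh + k * kw);
            if (h >= 0 && h < H && w >= 0 && w < W) {
              const double *s = xn + (R_xlen_t)C * (h + H * w);
              for (int c = 0; c < C; ++c) d[c] = s[c];
            } else {
              for (int c = 0; c < C; ++c) d[c] = 0.0;
            }
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add inverse of im2col: accumulates column-matrix gradients back
// onto the [C, H, W, N] input gradient.
// [[Rcpp::export]]
NumericVector col2im_nchw(NumericMatrix cols, int C, int H, int W, int N,
                          int k, int stride, int pad) {
  const int outH = (H + 2 * pad - k) / stride + 1;
  const int outW = (W + 2 * pad - k) / stride + 1;
  const int rows = C * k * k;
  NumericVector x((R_xlen_t)C * H * W * N);
  double *xp = x.begin();
  const double *cp = cols.begin();
  for (int n = 0; n < N; ++n) {
    double *xn = xp + (R_xlen_t)n * C * H * W;
    for (int wo = 0; wo < outW; ++wo) {
      for (int ho = 0; ho < outH; ++ho) {
        const R_xlen_t col = (R_xlen_t)n * outH * outW + (R_xlen_t)wo * outH + ho;
        const double *src = cp + col * rows;
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int kw = 0; kw < k; ++kw) {
          const int w = w0 + kw;
          if (w < 0 || w >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int h = h0 + kh;
            if (h < 0 || h >= H) continue;
            const double *s = src + (R_xlen_t)C * (kh + k * kw);
            double *d = xn + (R_xlen_t)C * (h + H * w);
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
      }
    }
  }
  return x;
}

// Max pooling over [C, H, W, N]; returns pooled values and 1-based argmax
// indices into the input vector (for the backward scatter).
// [[Rcpp::export]]
List maxpool_fwd(NumericVector x, int C, int H, int W, int N,
                 int k, int stride, int pad) {
  const int outH = (H + 2 * pad - k) / stride + 1;
  const int outW = (W + 2 * pad - k) / stride + 1;
  NumericVector y((R_xlen_t)C * outH * outW * N);
  IntegerVector arg((R_xlen_t)C * outH * outW * N);
  const double *xp = x.begin();
  double *yp = y.begin();
  int *ap = arg.begin();
  for (int n = 0; n < N; ++n) {
    const R_xlen_t xoff = (R_xlen_t)n * C * H * W;
    for (int wo = 0; wo < outW; ++wo) {
      for (int ho = 0; ho < outH; ++ho) {
        const R_xlen_t yoff =
            (R_xlen_t)C * (ho + (R_xlen_t)outH * (wo + (R_xlen_t)outW * n));
        const int h0 = ho * stride - pad;
        const int w0 = wo * stride - pad;
        for (int c = 0; c < C; ++c) {
          double best = R_NegInf;
          R_xlen_t bestIdx = -1;
          for (int kw = 0; kw < k; ++kw) {
            const int w = w0 + kw;
            if (w < 0 || w >= W) continue;
            for (int kh = 0; kh < k; ++kh) {
              const int h = h0 + kh;
              if (h < 0 || h >= H) continue;
              const R_xlen_t idx = xoff + c + (R_xlen_t)C * (h + H * w);
              if (xp[idx] > best) { best = xp[idx]; bestIdx = idx; }
            }
          }
          yp[yoff + c] = best;
          ap[yoff + c] = (int)(bestIdx + 1);
        }
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(NumericVector dy, IntegerVector argmax, R_xlen_t len) {
  NumericVector dx(len);
  double *dp = dx.begin();
  const double *gp = dy.begin();
  const int *ap = argmax.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) dp[ap[i] - 1] += gp[i];
  return dx;
}
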