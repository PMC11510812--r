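// Building blocks for the small convolutional network: 3x3 im2col/col2im
// (zero padding 1, stride 1) and 2x2 max pooling.  Tensors are column-major
// R arrays with layout (H, W, N, C): rows, columns, batch sample, channel.
//
// im2col uses the transposed patch-matrix layout (H*W*N) x (C*9): the
// convolution is then `cols %*% t(W)` whose result vector is already in
// (H, W, N, C_out) order, so neither pass needs a large transpose.  The
// matrix products themselves run in R via BLAS.

#include <Rcpp.h>
using namespace Rcpp;

// x: (H, W, N, C) -> cols: (H*W*N) x (C*9), patch column index = c*9 + ky*3+kx
// [[Rcpp::export(name = ".cpp_im2col3")]]
NumericMatrix cpp_im2col3(NumericVector x, int h, int w, int n, int c) {
  const R_xlen_t plane = (R_xlen_t)h * w;
  const R_xlen_t m = plane * n;
  NumericMatrix cols(m, c * 9);
  const double *px = x.begin();
  double *pc = cols.begin();
  for (int cc = 0; cc < c; ++cc) {
    const R_xlen_t xoff_c = (R_xlen_t)cc * m;
    for (int ky = -1; ky <= 1; ++ky) {
      for (int kx = -1; kx <= 1; ++kx) {
        double *col = pc + m * (cc * 9 + (ky + 1) * 3 + (kx + 1));
        for (int s = 0; s < n; ++s) {
          const double *xs = px + xoff_c + (R_xlen_t)s * plane;
          double *cs = col + (R_xlen_t)s * plane;
          const int j0 = (kx < 0) ? 1 : 0, j1 = (kx > 0) ? w - 1 : w;
          const int i0 = (ky < 0) ? 1 : 0, i1 = (ky > 0) ? h - 1 : h;
          for (int j = j0; j < j1; ++j) {
            const double *src = xs + (R_xlen_t)h * (j + kx) + ky;
            double *dst = cs + (R_xlen_t)h * j;
            for (int i = i0; i < i1; ++i) dst[i] = src[i];
          }
        }
      }
    }
  }
  return cols;
}

// adjoint of im2col: patch-matrix gradient -> input gradient (H, W, N, C)
// [[Rcpp::export(name = ".cpp_col2im3")]]
NumericVector cpp_col2im3(NumericMatrix cols, int h, int w, int n, int c) {
  const R_xlen_t plane = (R_xlen_t)h * w;
  const R_xlen_t m = plane * n;
  NumericVector dx(m * c);
  const double *pc = cols.begin();
  double *px = dx.begin();
  for (int cc = 0; cc < c; ++cc) {
    const R_xlen_t xoff_c = (R_xlen_t)cc * m;
    for (int ky = -1; ky <= 1; ++ky) {
      for (int kx = -1; kx <= 1; ++kx) {
        const double *col = pc + m * (cc * 9 + (ky + 1) * 3 + (kx + 1));
        for (int s = 0; s < n; ++s) {
          double *xs = px + xoff_c + (R_xlen_t)s * plane;
          const double *cs = col + (R_xlen_t)s * plane;
          const int j0 = (kx < 0) ? 1 : 0, j1 = (kx > 0) ? w - 1 : w;
          const int i0 = (ky < 0) ? 1 : 0, i1 = (ky > 0) ? h - 1 : h;
          for (int j = j0; j < j1; ++j) {
            double *dst = xs + (R_xlen_t)h * (j + kx) + ky;
            const double *src = cs + (R_xlen_t)h * j;
            for (int i = i0; i < i1; ++i) dst[i] += src[i];
          }
        }
      }
    }
  }
  return dx;
}

// 2x2 max pooling, stride 2; returns pooled values and 1-based argmax indices
// into the input vector (for the backward scatter)
// [[Rcpp::export(name = ".cpp_maxpool2")]]
List cpp_maxpool2(NumericVector x, int h, int w, int n, int c) {
  const int ho = h / 2, wo = w / 2;
  NumericVector y((R_xlen_t)ho * wo * n * c);
  IntegerVector arg(y.size());
  const double *px = x.begin();
  double *py = y.begin();
  int *pa = arg.begin();
  R_xlen_t o = 0;
  for (int cc = 0; cc < c; ++cc)
    for (int s = 0; s < n; ++s) {
      const R_xlen_t base = ((R_xlen_t)cc * n + s) * h * w;
      for (int j = 0; j < wo; ++j)
        for (int i = 0; i < ho; ++i, ++o) {
          R_xlen_t best = base + (R_xlen_t)2 * i + (R_xlen_t)h * 2 * j;
          double bv = px[best];
          const R_xlen_t cand[3] = {best + 1, best + h, best + h + 1};
          for (int k = 0; k < 3; ++k)
            if (px[cand[k]] > bv) { bv = px[cand[k]]; best = cand[k]; }
          py[o] = bv;
          pa[o] = (int)(best + 1);
        }
    }
  return List::create(Named("y") = y, Named("argmax") = arg);
}

// backward of 2x2 max pooling
// [[Rcpp::export(name = ".cpp_maxpool2_bwd")]]
NumericVector cpp_maxpool2_bwd(NumericVector dy, IntegerVector argmax,
                               R_xlen_t input_len) {
  NumericVector dx(input_len);
  const double *pd = dy.begin();
  const int *pa = argmax.begin();
  double *px = dx.begin();
  for (R_xlen_t k = 0; k < dy.size(); ++k) px[pa[k] - 1] += pd[k];
  return dx;
}

// fused batch-norm scale: y = (x - mu[c]) * s[c] * gamma[c] + beta[c]
// [[Rcpp::export(name = ".cpp_bn_apply")]]
NumericVector cpp_bn_apply(NumericVector x, R_xlen_t m, NumericVector mu,
                           NumericVector sc, NumericVector beta) {
  const int c = mu.size();
  NumericVector y(x.size());
  const double *px = x.begin();
  double *py = y.begin();
  for (int cc = 0; cc < c; ++cc) {
    const double mm = mu[cc], ss = sc[cc], bb = beta[cc];
    const double *xs = px + (R_xlen_t)cc * m;
    double *ys = py + (R_xlen_t)cc * m;
    for (R_xlen_t i = 0; i < m; ++i) ys[i] = (xs[i] - mm) * ss + bb;
  }
  return y;
}
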