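// Low-level kernels for the 1-D convolution layers.
//
// Feature maps are stored as (B*n) x C matrices with position fastest within
// sample (row = (b-1)*n + pos), R column-major. Convolutions themselves run
// as BLAS GEMM on the R side; these kernels only do the data movement that
// dominated the pure-R implementation: im2col gathers, col2im scatter-adds,
// fused bias+ReLU, and global max pooling with argmax bookkeeping.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <algorithm>
#include <cmath>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// im2col for an odd kernel size k with zero "same" padding: out column block
// t (size C) holds the input shifted by offset d = t - (k-1)/2, zeroed where
// pos + d falls outside [1, n].
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& m, int k, int n, int B) {
  const int C = m.ncol();
  const R_xlen_t nr = m.nrow();
  if (nr != (R_xlen_t)n * B) stop("im2col: bad layout");
  NumericMatrix out(nr, (R_xlen_t)k * C);
  const int half = (k - 1) / 2;
  for (int t = 0; t < k; ++t) {
    const int d = t - half;
    const int lo = std::max(0, -d), hi = std::min(n, n - d);
    for (int c = 0; c < C; ++c) {
      const double* src = &m(0, c);
      double* dst = &out(0, (R_xlen_t)t * C + c);
      for (int b = 0; b < B; ++b) {
        const double* s = src + (R_xlen_t)b * n;
        double* o = dst + (R_xlen_t)b * n;
        for (int p = 0; p < lo; ++p) o[p] = 0.0;
        for (int p = lo; p < hi; ++p) o[p] = s[p + d];
        for (int p = hi; p < n; ++p) o[p] = 0.0;
      }
    }
  }
  return out;
}

// Adjoint of cpp_im2col: scatter-add the k column blocks of the upstream
// gradient back onto a (B*n) x C map.
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dcols, int k, int n, int B,
                         int C) {
  const R_xlen_t nr = dcols.nrow();
  if (nr != (R_xlen_t)n * B || dcols.ncol() != (R_xlen_t)k * C)
    stop("col2im: bad layout");
  NumericMatrix out(nr, C);  // zero-initialised
  const int half = (k - 1) / 2;
  for (int t = 0; t < k; ++t) {
    const int d = t - half;
    const int lo = std::max(0, -d), hi = std::min(n, n - d);
    for (int c = 0; c < C; ++c) {
      const double* src = &dcols(0, (R_xlen_t)t * C + c);
      double* dst = &out(0, c);
      for (int b = 0; b < B; ++b) {
        const double* s = src + (R_xlen_t)b * n;
        double* o = dst + (R_xlen_t)b * n;
        for (int p = lo; p < hi; ++p) o[p + d] += s[p];
      }
    }
  }
  return out;
}

// In-place fused bias add + optional ReLU on a freshly allocated GEMM result
// (the caller owns z; no other reference exists).
// [[Rcpp::export]]
void cpp_add_bias_relu(NumericMatrix z, const NumericVector& b, bool relu) {
  const R_xlen_t nr = z.nrow();
  const int nc = z.ncol();
  if (b.size() != nc) stop("bias length mismatch");
  for (int c = 0; c < nc; ++c) {
    double* col = &z(0, c);
    const double bc = b[c];
    if (relu) {
      for (R_xlen_t r = 0; r < nr; ++r) {
        const double v = col[r] + bc;
        col[r] = v > 0.0 ? v : 0.0;
      }
    } else {
      for (R_xlen_t r = 0; r < nr; ++r) col[r] += bc;
    }
  }
}

// One Adam step on a single parameter leaf, updating param, m and v in place
// (the training loop owns deep copies of all three; g is consumed before the
// next batch overwrites it). Avoids reallocating the 4 full-size parameter
// trees per mini-batch that a pure-R update would create.
// [[Rcpp::export]]
void cpp_adam_update(NumericVector param, NumericVector m, NumericVector v,
                     const NumericVector& g, double lr, double beta1,
                     double beta2, double eps, int t) {
  const R_xlen_t n = param.size();
  if (m.size() != n || v.size() != n || g.size() != n)
    stop("adam: length mismatch");
  const double c1 = 1.0 - std::pow(beta1, (double)t);
  const double c2 = 1.0 - std::pow(beta2, (double)t);
  // step = lr * (m/c1) / (sqrt(v/c2) + eps), with the per-element divisions
  // by c1 and c2 hoisted into constants
  const double a = lr / c1;
  const double s2 = 1.0 / std::sqrt(c2);
  const double om1 = 1.0 - beta1, om2 = 1.0 - beta2;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double gi = g[i];
    const double mi = beta1 * m[i] + om1 * gi;
    const double vi = beta2 * v[i] + om2 * gi * gi;
    m[i] = mi;
    v[i] = vi;
    param[i] -= a * mi / (std::sqrt(vi) * s2 + eps);
  }
}

// c := t(a) %*% b written into a preallocated buffer, so the large fully
// connected weight gradients are not reallocated on every mini-batch.
// [[Rcpp::export]]
void cpp_crossprod_into(const NumericMatrix& a, const NumericMatrix& b,
                        NumericMatrix c) {
  const int m = a.ncol(), k = a.nrow(), n = b.ncol();
  if (b.nrow() != k || c.nrow() != m || c.ncol() != n)
    stop("crossprod_into: shape mismatch");
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("T", "N", &m, &n, &k, &one, a.begin(), &k, b.begin(), &k,
                  &zero, c.begin(), &m FCONE FCONE);
}

// cpp_im2col writing into a caller-owned buffer, so the large gathered
// matrices are not reallocated (and page-faulted) on every mini-batch.
// [[Rcpp::export]]
void cpp_im2col_into(const NumericMatrix& m, int k, int n, int B,
                     NumericMatrix out) {
  const int C = m.ncol();
  const R_xlen_t nr = m.nrow();
  if (nr != (R_xlen_t)n * B) stop("im2col: bad layout");
  if (out.nrow() != nr || out.ncol() != (R_xlen_t)k * C)
    stop("im2col_into: bad buffer shape");
  const int half = (k - 1) / 2;
  for (int t = 0; t < k; ++t) {
    const int d = t - half;
    const int lo = std::max(0, -d), hi = std::min(n, n - d);
    for (int c = 0; c < C; ++c) {
      const double* src = &m(0, c);
      double* dst = &out(0, (R_xlen_t)t * C + c);
      for (int b = 0; b < B; ++b) {
        const double* s = src + (R_xlen_t)b * n;
        double* o = dst + (R_xlen_t)b * n;
        for (int p = 0; p < lo; ++p) o[p] = 0.0;
        for (int p = lo; p < hi; ++p) o[p] = s[p + d];
        for (int p = hi; p < n; ++p) o[p] = 0.0;
      }
    }
  }
}

// c := a %*% t(b) written into a preallocated buffer.
// [[Rcpp::export]]
void cpp_tcrossprod_into(const NumericMatrix& a, const NumericMatrix& b,
                         NumericMatrix c) {
  const int m = a.nrow(), k = a.ncol(), n = b.nrow();
  if (b.ncol() != k || c.nrow() != m || c.ncol() != n)
    stop("tcrossprod_into: shape mismatch");
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "T", &m, &n, &k, &one, a.begin(), &m, b.begin(), &n,
                  &zero, c.begin(), &m FCONE FCONE);
}

// dst[, col0+1 .. col0+ncol(w)] := a %*% w + bias (optionally ReLU), written
// in place into a caller-owned buffer. Fuses the convolution-as-GEMM with the
// activation and avoids allocating the feature map on every mini-batch.
// col0 is 0-based.
// [[Rcpp::export]]
void cpp_gemm_bias_relu_into_cols(const NumericMatrix& a,
                                  const NumericMatrix& w,
                                  const NumericVector& bias, bool relu,
                                  NumericMatrix dst, int col0) {
  const int m = a.nrow(), k = a.ncol(), n = w.ncol();
  if (w.nrow() != k || dst.nrow() != m || col0 < 0 ||
      (R_xlen_t)col0 + n > dst.ncol() || bias.size() != n)
    stop("gemm_into_cols: shape mismatch");
  double* c = dst.begin() + (R_xlen_t)col0 * m;
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &m, &n, &k, &one, a.begin(), &m, w.begin(), &k,
                  &zero, c, &m FCONE FCONE);
  for (int j = 0; j < n; ++j) {
    double* col = c + (R_xlen_t)j * m;
    const double bj = bias[j];
    if (relu) {
      for (int r = 0; r < m; ++r) {
        const double v = col[r] + bj;
        col[r] = v > 0.0 ? v : 0.0;
      }
    } else {
      for (int r = 0; r < m; ++r) col[r] += bj;
    }
  }
}

// Global max pooling over positions: P[b, f] = max_p A[(b-1)*n + p, f], with
// the 1-based argmax position (first maximum on ties).
// [[Rcpp::export]]
List cpp_pool_max(const NumericMatrix& a, int n, int B) {
  const int F = a.ncol();
  if (a.nrow() != (R_xlen_t)n * B) stop("pool: bad layout");
  NumericMatrix P(B, F);
  IntegerMatrix idx(B, F);
  for (int f = 0; f < F; ++f) {
    const double* col = &a(0, f);
    for (int b = 0; b < B; ++b) {
      const double* s = col + (R_xlen_t)b * n;
      int am = 0;
      double mx = s[0];
      for (int p = 1; p < n; ++p)
        if (s[p] > mx) { mx = s[p]; am = p; }
      P(b, f) = mx;
      idx(b, f) = am + 1;
    }
  }
  return List::create(_["P"] = P, _["idx"] = idx);
}
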