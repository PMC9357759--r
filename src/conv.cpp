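// Temporal 1-D convolution along the frame axis, implemented as one BLAS
// dgemm per kernel tap on a zero-padded copy of the input. Activations are
// column-major matrices of shape (C, VN*T) with the joint/person composite
// index fastest and the frame index slowest, so a shift in time is a pure
// column offset and every tap multiplies a contiguous submatrix in place.

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <vector>
#include <algorithm>

using namespace Rcpp;

static void pad_time(const double* x, std::vector<double>& xp, int c_n,
                     int vn, int t_n, int k, int left) {
  xp.assign((size_t)c_n * vn * (t_n + k - 1), 0.0);
  std::copy(x, x + (size_t)c_n * vn * t_n,
            xp.data() + (size_t)left * vn * c_n);
}

// y[o, (vn, t)] = bias[o] + sum_kk sum_c w[o, c, kk] * x[c, (vn, t + kk - left)]
// [[Rcpp::export(name = ".cpp_tconv_fwd")]]
NumericMatrix cpp_tconv_fwd(NumericVector x, NumericVector w,
                            NumericVector bias, int c_in, int vn, int t_n,
                            int c_out, int k, int left) {
  std::vector<double> xp;
  pad_time(x.begin(), xp, c_in, vn, t_n, k, left);
  NumericMatrix y(c_out, vn * t_n);
  const int n_cols = vn * t_n;
  const double one = 1.0, zero = 0.0;
  for (int kk = 0; kk < k; ++kk) {
    const double beta = kk == 0 ? zero : one;
    F77_CALL(dgemm)("N", "N", &c_out, &n_cols, &c_in, &one,
                    w.begin() + (size_t)kk * c_out * c_in, &c_out,
                    xp.data() + (size_t)kk * vn * c_in, &c_in, &beta,
                    y.begin(), &c_out FCONE FCONE);
  }
  double* py = y.begin();
  for (int j = 0; j < n_cols; ++j)
    for (int o = 0; o < c_out; ++o) py[(size_t)j * c_out + o] += bias[o];
  return y;
}

// input gradient: dx[c, (vn, t2)] += sum_kk sum_o w[o, c, kk] * dy[o, (vn, t)]
// [[Rcpp::export(name = ".cpp_tconv_bwd_dx")]]
NumericMatrix cpp_tconv_bwd_dx(NumericVector dy, NumericVector w, int c_in,
                               int vn, int t_n, int c_out, int k, int left) {
  std::vector<double> dxp((size_t)c_in * vn * (t_n + k - 1), 0.0);
  const int n_cols = vn * t_n;
  const double one = 1.0;
  for (int kk = 0; kk < k; ++kk) {
    F77_CALL(dgemm)("T", "N", &c_in, &n_cols, &c_out, &one,
                    w.begin() + (size_t)kk * c_out * c_in, &c_out,
                    dy.begin(), &c_out, &one,
                    dxp.data() + (size_t)kk * vn * c_in, &c_in FCONE FCONE);
  }
  NumericMatrix dx(c_in, n_cols);
  std::copy(dxp.data() + (size_t)left * vn * c_in,
            dxp.data() + (size_t)(left * vn + (size_t)n_cols) * c_in,
            dx.begin());
  return dx;
}

// weight gradient: dw[o, c, kk] = sum_{vn,t} dy[o, (vn, t)] * xp[c, (vn, t + kk)]
// [[Rcpp::export(name = ".cpp_tconv_bwd_dw")]]
NumericVector cpp_tconv_bwd_dw(NumericVector dy, NumericVector x, int c_in,
                               int vn, int t_n, int c_out, int k, int left) {
  std::vector<double> xp;
  pad_time(x.begin(), xp, c_in, vn, t_n, k, left);
  NumericVector dw((size_t)c_out * c_in * k);
  const int n_cols = vn * t_n;
  const double one = 1.0, zero = 0.0;
  for (int kk = 0; kk < k; ++kk) {
    F77_CALL(dgemm)("N", "T", &c_out, &c_in, &n_cols, &one, dy.begin(),
                    &c_out, xp.data() + (size_t)kk * vn * c_in, &c_in, &zero,
                    dw.begin() + (size_t)kk * c_out * c_in,
                    &c_out FCONE FCONE);
  }
  return dw;
}
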