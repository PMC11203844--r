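// Compiled kernels for the 1D convolution layers: sliding-window
// gather/scatter (im2col and its adjoint) and max-pooling with winner
// tracking. Matrix products stay in R (BLAS). All layouts are
// column-major with the sample index fastest:
//   X:   n x (L*C), column (pos)*C + c        (position-major, 0-based)
//   M:   (n*conv_L) x (k*C), row i + p*n
//   H/Z: (n*conv_L) x F
//   A:   n x (out_L*F), column p*F + f        (pool output)

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix conv_im2col(const NumericMatrix& X, int C, int k,
                          int conv_L) {
  const int n = X.nrow();
  const int kC = k * C;
  NumericMatrix M(n * conv_L, kC);
  const double* x = X.begin();
  double* m = M.begin();
  const R_xlen_t mrows = (R_xlen_t)n * conv_L;
  for (int j = 0; j < kC; ++j) {
    for (int p = 0; p < conv_L; ++p) {
      const double* src = x + (R_xlen_t)(p * C + j) * n;
      double* dst = m + (R_xlen_t)j * mrows + (R_xlen_t)p * n;
      std::copy(src, src + n, dst);
    }
  }
  return M;
}

// adjoint of conv_im2col: scatter-add window gradients back to inputs
// [[Rcpp::export]]
NumericMatrix conv_col2im(const NumericMatrix& dM, int n, int L, int C,
                          int k) {
  const int kC = k * C;
  const int conv_L = L - k + 1;
  NumericMatrix dX(n, L * C);
  const double* dm = dM.begin();
  double* dx = dX.begin();
  const R_xlen_t mrows = (R_xlen_t)n * conv_L;
  for (int j = 0; j < kC; ++j) {
    for (int p = 0; p < conv_L; ++p) {
      const double* src = dm + (R_xlen_t)j * mrows + (R_xlen_t)p * n;
      double* dst = dx + (R_xlen_t)(p * C + j) * n;
      for (int i = 0; i < n; ++i) dst[i] += src[i];
    }
  }
  return dX;
}

// max-pool over positions; returns pooled activations and 1-based
// winner offsets within each window
// [[Rcpp::export]]
List conv_pool_fwd(const NumericMatrix& H, int n, int conv_L, int pool,
                   int out_L) {
  const int F = H.ncol();
  NumericMatrix A(n, out_L * F);
  IntegerMatrix win(n, out_L * F);
  const double* h = H.begin();
  const R_xlen_t hrows = (R_xlen_t)n * conv_L;
  for (int f = 0; f < F; ++f) {
    const double* hf = h + (R_xlen_t)f * hrows;
    for (int p = 0; p < out_L; ++p) {
      const int acol = p * F + f;
      double* a = A.begin() + (R_xlen_t)acol * n;
      int* w = win.begin() + (R_xlen_t)acol * n;
      for (int i = 0; i < n; ++i) {
        double best = hf[(R_xlen_t)(p * pool) * n + i];
        int bo = 1;
        for (int o = 1; o < pool; ++o) {
          double v = hf[(R_xlen_t)(p * pool + o) * n + i];
          if (v > best) { best = v; bo = o + 1; }
        }
        a[i] = best;
        w[i] = bo;
      }
    }
  }
  return List::create(_["A"] = A, _["win"] = win);
}

// route pooled gradients (or relevance) back to the winning positions
// [[Rcpp::export]]
NumericMatrix conv_pool_bwd(const NumericMatrix& dA,
                            const IntegerMatrix& win, int n, int conv_L,
                            int pool, int out_L) {
  const int F = dA.ncol() / out_L;
  NumericMatrix dH(n * conv_L, F);
  const double* da = dA.begin();
  const int* w = win.begin();
  double* dh = dH.begin();
  const R_xlen_t hrows = (R_xlen_t)n * conv_L;
  for (int f = 0; f < F; ++f) {
    double* dhf = dh + (R_xlen_t)f * hrows;
    for (int p = 0; p < out_L; ++p) {
      const R_xlen_t acol = (R_xlen_t)(p * F + f) * n;
      for (int i = 0; i < n; ++i) {
        const int o = w[acol + i] - 1;
        dhf[(R_xlen_t)(p * pool + o) * n + i] += da[acol + i];
      }
    }
  }
  return dH;
}
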