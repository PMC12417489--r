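// Hot-path tensor kernels for the convolutional stack. Everything here is
// layout shuffling (im2col / col2im and the block-1 permutes); the actual
// arithmetic stays in BLAS on the R side.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// x: (C, T, N) column-major -> M: (C*k, Tout*N), Tout = T - k + 1.
// Row index of M is c + C*j (tap j = 0..k-1), column index t + Tout*u.
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int C, int T, int N, int k) {
  const int Tout = T - k + 1;
  NumericMatrix M(C * k, Tout * N);
  const double* xp = x.begin();
  double* mp = M.begin();
  const size_t Ck = (size_t)C * k;
  for (int u = 0; u < N; ++u) {
    const double* xu = xp + (size_t)C * T * u;
    double* mu = mp + Ck * (size_t)Tout * u;
    for (int t = 0; t < Tout; ++t) {
      double* mcol = mu + Ck * t;
      for (int j = 0; j < k; ++j) {
        std::memcpy(mcol + (size_t)C * j, xu + (size_t)C * (t + j),
                    sizeof(double) * C);
      }
    }
  }
  return M;
}

// adjoint of cpp_im2col: scatter-add dM back onto the input layout
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix dM, int C, int T, int N, int k) {
  const int Tout = T - k + 1;
  NumericVector dx((size_t)C * T * N);
  const double* mp = dM.begin();
  double* xp = dx.begin();
  const size_t Ck = (size_t)C * k;
  for (int u = 0; u < N; ++u) {
    double* xu = xp + (size_t)C * T * u;
    const double* mu = mp + Ck * (size_t)Tout * u;
    for (int t = 0; t < Tout; ++t) {
      const double* mcol = mu + Ck * t;
      for (int j = 0; j < k; ++j) {
        double* dst = xu + (size_t)C * (t + j);
        const double* src = mcol + (size_t)C * j;
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
    }
  }
  return dx;
}

// (F, T1, C, N) -> (F*C, T1, N): gather electrodes next to features for the
// spatial convolution of block 1.
// [[Rcpp::export]]
NumericVector cpp_gather_spatial(NumericVector h, int F, int T1, int C,
                                 int N) {
  NumericVector out((size_t)F * C * T1 * N);
  const double* hp = h.begin();
  double* op = out.begin();
  for (int u = 0; u < N; ++u) {
    for (int c = 0; c < C; ++c) {
      const double* src = hp + (size_t)F * T1 * (c + (size_t)C * u);
      for (int t = 0; t < T1; ++t) {
        std::memcpy(op + (size_t)F * (c + (size_t)C * (t + (size_t)T1 * u)),
                    src + (size_t)F * t, sizeof(double) * F);
      }
    }
  }
  return out;
}

// adjoint of cpp_gather_spatial: (F*C, T1, N) -> (F, T1, C, N)
// [[Rcpp::export]]
NumericVector cpp_scatter_spatial(NumericVector g, int F, int T1, int C,
                                  int N) {
  NumericVector out((size_t)F * T1 * C * N);
  const double* gp = g.begin();
  double* op = out.begin();
  for (int u = 0; u < N; ++u) {
    for (int c = 0; c < C; ++c) {
      double* dst = op + (size_t)F * T1 * (c + (size_t)C * u);
      for (int t = 0; t < T1; ++t) {
        std::memcpy(dst + (size_t)F * t,
                    gp + (size_t)F * (c + (size_t)C * (t + (size_t)T1 * u)),
                    sizeof(double) * F);
      }
    }
  }
  return out;
}

// batch assembly: copy window w (C, T) of a recording into slot i of the
// (T, C, n) training batch
// [[Rcpp::export]]
void cpp_fill_batch(NumericVector bx, NumericMatrix w, int T, int C, int i) {
  double* bp = bx.begin() + (size_t)T * C * i;
  const double* wp = w.begin();   // (C, T) column-major: w[c + C*t]
  for (int t = 0; t < T; ++t) {
    for (int c = 0; c < C; ++c) bp[t + (size_t)T * c] = wp[c + (size_t)C * t];
  }
}
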