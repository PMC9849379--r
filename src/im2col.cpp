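#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Feature maps are stored as (C x H*W*N) matrices, columns ordered with the
// spatial row index fastest, then spatial column, then batch element.
// im2col builds the (C*k*k x Ho*Wo*N) patch matrix for a k x k kernel with
// symmetric zero padding; rows ordered channel fastest, then kernel row,
// then kernel column.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericMatrix M, int H, int W, int N, int k,
                         int pad) {
  const int C = M.nrow();
  if ((long)M.ncol() != (long)H * W * N) stop("im2col: shape mismatch");
  const int Ho = H + 2 * pad - k + 1;
  const int Wo = W + 2 * pad - k + 1;
  if (Ho < 1 || Wo < 1) stop("kernel larger than padded input");
  NumericMatrix X(C * k * k, (long)Ho * Wo * N);
  const double* src = M.begin();
  double* dst = X.begin();
  const long xrows = (long)C * k * k;
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const long col = i + (long)Ho * (j + (long)Wo * n);
        for (int dv = 0; dv < k; ++dv) {
          const int sj = j + dv - pad;
          if (sj < 0 || sj >= W) continue;
          for (int du = 0; du < k; ++du) {
            const int si = i + du - pad;
            if (si < 0 || si >= H) continue;
            const long scol = si + (long)H * (sj + (long)W * n);
            std::memcpy(dst + col * xrows + (long)C * (du + k * dv),
                        src + scol * C, C * sizeof(double));
          }
        }
      }
    }
  }
  return X;
}

// Adjoint of im2col: scatter-add patch-matrix gradients back to the
// (C x H*W*N) layout.
// [[Rcpp::export]]
NumericMatrix col2im_cpp(NumericMatrix dX, int H, int W, int N, int k,
                         int pad) {
  const int Ho = H + 2 * pad - k + 1;
  const int Wo = W + 2 * pad - k + 1;
  const int C = dX.nrow() / (k * k);
  if ((long)dX.ncol() != (long)Ho * Wo * N) stop("col2im: shape mismatch");
  NumericMatrix dM(C, (long)H * W * N);
  const double* src = dX.begin();
  double* dst = dM.begin();
  const long xrows = (long)C * k * k;
  for (int n = 0; n < N; ++n) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const long col = i + (long)Ho * (j + (long)Wo * n);
        for (int dv = 0; dv < k; ++dv) {
          const int sj = j + dv - pad;
          if (sj < 0 || sj >= W) continue;
          for (int du = 0; du < k; ++du) {
            const int si = i + du - pad;
            if (si < 0 || si >= H) continue;
            const long scol = si + (long)H * (sj + (long)W * n);
            const double* s = src + col * xrows + (long)C * (du + k * dv);
            double* d = dst + scol * C;
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
      }
    }
  }
  return dM;
}
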