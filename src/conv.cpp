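// Hot inner kernels of the frame classifier: im2col for 3x3 same-padded
// convolution and the array reshapes around the BLAS matrix products.
#include <Rcpp.h>
using namespace Rcpp;

// x: (H, W, C, N) column-major; returns (9C) x (H*W*N) patch matrix with
// rows ordered r = c*9 + (j+1)*3 + (i+1) (offsets i, j in -1..1), matching
// the weight layout used on the R side. Zero padding is implicit.
// [[Rcpp::export]]
NumericMatrix cppIm2col3(NumericVector x, int H, int W, int C, int N) {
  NumericMatrix out(9 * C, H * W * N);
  double* po = out.begin();
  const double* px = x.begin();
  const int rows = 9 * C;
  for (int n = 0; n < N; ++n) {
    for (int w = 0; w < W; ++w) {
      for (int h = 0; h < H; ++h) {
        double* col = po + (size_t)rows * (h + (size_t)H * (w + (size_t)W * n));
        for (int c = 0; c < C; ++c) {
          const double* xc = px + (size_t)H * W * (c + (size_t)C * n);
          int r = 9 * c;
          for (int j = -1; j <= 1; ++j) {
            const int ww = w + j;
            const bool wok = ww >= 0 && ww < W;
            for (int i = -1; i <= 1; ++i) {
              const int hh = h + i;
              col[r++] = (wok && hh >= 0 && hh < H) ? xc[hh + H * ww] : 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// outMat: F x (H*W*N) -> array (H, W, F, N)
// [[Rcpp::export]]
NumericVector cppConvOut(NumericMatrix outMat, int H, int W, int F, int N) {
  NumericVector out((size_t)H * W * F * N);
  double* po = out.begin();
  const double* pm = outMat.begin();
  for (int n = 0; n < N; ++n)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const double* colp = pm + (size_t)F * (h + (size_t)H * (w + (size_t)W * n));
        for (int f = 0; f < F; ++f)
          po[h + (size_t)H * (w + (size_t)W * (f + (size_t)F * n))] = colp[f];
      }
  out.attr("dim") = IntegerVector::create(H, W, F, N);
  return out;
}

// dOut: (H, W, F, N) -> matrix F x (H*W*N), channels-first per position
// [[Rcpp::export]]
NumericMatrix cppChannelsFirst(NumericVector dOut, int H, int W, int F, int N) {
  NumericMatrix out(F, H * W * N);
  double* po = out.begin();
  const double* px = dOut.begin();
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f) {
      const double* xf = px + (size_t)H * W * (f + (size_t)F * n);
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h)
          po[f + (size_t)F * (h + (size_t)H * (w + (size_t)W * n))] =
            xf[h + (size_t)H * w];
    }
  return out;
}
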