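#include <Rcpp.h>
using namespace Rcpp;

// Separable 1-D convolution along one axis of a 3-D array stored in
// column-major order, with nearest-edge (replicate) border handling.
// axis: 0 = x (fastest), 1 = y, 2 = z. Kernel length must be odd.
// [[Rcpp::export]]
NumericVector conv_axis_replicate(const NumericVector& a,
                                  const IntegerVector& dim,
                                  const NumericVector& kernel,
                                  const int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kl = kernel.size();
  if (kl % 2 == 0) stop("kernel length must be odd");
  if (axis < 0 || axis > 2) stop("axis must be 0, 1 or 2");
  const int kr = kl / 2;
  NumericVector out(no_init(a.size()));
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) {
        double s = 0.0;
        for (int t = -kr; t <= kr; ++t) {
          int ii = i, jj = j, kk = k;
          if (axis == 0) {
            ii += t; if (ii < 0) ii = 0; else if (ii >= nx) ii = nx - 1;
          } else if (axis == 1) {
            jj += t; if (jj < 0) jj = 0; else if (jj >= ny) jj = ny - 1;
          } else {
            kk += t; if (kk < 0) kk = 0; else if (kk >= nz) kk = nz - 1;
          }
          s += kernel[t + kr] * a[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
        }
        out[base + i] = s;
      }
    }
  }
  return out;
}
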