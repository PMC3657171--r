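#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation of a 3D array at continuous 0-based voxel
// coordinates, with zero fill outside the field of view.
// [[Rcpp::export]]
NumericVector interp_trilinear_cpp(NumericVector a, IntegerVector dims,
                                   NumericVector ci, NumericVector cj,
                                   NumericVector ck) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = ci.size();
  NumericVector out(n);
  const double *A = a.begin();
  for (R_xlen_t p = 0; p < n; ++p) {
    const double x = ci[p], y = cj[p], z = ck[p];
    const int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
              k0 = (int)std::floor(z);
    const double fi = x - i0, fj = y - j0, fk = z - k0;
    double v = 0.0;
    for (int dk = 0; dk <= 1; ++dk) {
      const int k = k0 + dk;
      if (k < 0 || k >= d3) continue;
      const double wk = dk ? fk : 1.0 - fk;
      for (int dj = 0; dj <= 1; ++dj) {
        const int j = j0 + dj;
        if (j < 0 || j >= d2) continue;
        const double wjk = wk * (dj ? fj : 1.0 - fj);
        const R_xlen_t base = (R_xlen_t)(k * d2 + j) * d1;
        for (int di = 0; di <= 1; ++di) {
          const int i = i0 + di;
          if (i < 0 || i >= d1) continue;
          v += wjk * (di ? fi : 1.0 - fi) * A[base + i];
        }
      }
    }
    out[p] = v;
  }
  return out;
}
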