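#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling on a logical 3-D array (column-major).
// Neighbourhood is the full 26-neighbourhood; for a single-plane input
// (nz == 1) this reduces to 8-connectivity in 2-D. Labels are assigned
// in raster-scan discovery order starting at 1, which makes label order
// deterministic (used for tie-breaking downstream).
// [[Rcpp::export]]
IntegerVector label_components(const LogicalVector& mask,
                               const IntegerVector& dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> todo;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    todo.push_back(s);
    while (!todo.empty()) {
      const R_xlen_t v = todo.back(); todo.pop_back();
      const int k = (int)(v / ((R_xlen_t)nx * ny));
      const int rem = (int)(v - (R_xlen_t)k * nx * ny);
      const int j = rem / nx, i = rem % nx;
      for (int dk = -1; dk <= 1; ++dk) {
        const int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            if (!di && !dj && !dk) continue;
            const R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[w] && !lab[w]) { lab[w] = next; todo.push_back(w); }
          }
        }
      }
    }
  }
  return lab;
}
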