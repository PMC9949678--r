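#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connectivity component labelling of a 3D logical array (flattened,
// column-major with dims d). Labels are 1..k in discovery order.
// [[Rcpp::export]]
IntegerVector label_components_26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      for (int dz = -1; dz <= 1; ++dz) {
        int zz = z + dz; if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
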