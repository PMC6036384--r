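#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 26-connected component labeling of a 3D logical mask.
// Labels are assigned in raster-scan order of each component's first voxel,
// which makes the labeling deterministic across platforms.
// [[Rcpp::export(name = ".cc_label26")]]
IntegerVector cc_label26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);
  int next_label = 0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (!mask[idx] || labels[idx] != 0) continue;
    ++next_label;
    labels[idx] = next_label;
    stack.push_back(idx);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int k = (int)(cur / sz);
      int rem = (int)(cur % sz);
      int j = rem / nx;
      int i = rem % nx;
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk;
        if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di;
            if (ii < 0 || ii >= nx) continue;
            R_xlen_t nb = (R_xlen_t)ii * sx + (R_xlen_t)jj * sy + (R_xlen_t)kk * sz;
            if (mask[nb] && labels[nb] == 0) {
              labels[nb] = next_label;
              stack.push_back(nb);
            }
          }
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}
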