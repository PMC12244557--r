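#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labelling, 6- or 26-connectivity.
// Labels are assigned 1..K in array-linear (raster) order of each
// component's first voxel, so the result is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity = 26) {
  int ny = dim[0], nx = dim[1], nz = dim[2];
  R_xlen_t nn = (R_xlen_t)ny * nx * nz;
  IntegerVector lab(nn); // zero-initialised
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);

  // neighbour offsets
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        int manh = std::abs(dy) + std::abs(dx) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dy, dx, dz});
      }

  int next = 0;
  R_xlen_t stride = (R_xlen_t)ny * nx;
  for (R_xlen_t start = 0; start < nn; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++next;
    lab[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int k = (int)(cur / stride);
      int rem = (int)(cur % stride);
      int j = rem / ny, i = rem % ny;
      for (const auto &o : offs) {
        int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || ii >= ny || jj < 0 || jj >= nx || kk < 0 || kk >= nz) continue;
        R_xlen_t idx = (R_xlen_t)kk * stride + (R_xlen_t)jj * ny + ii;
        if (mask[idx] && lab[idx] == 0) { lab[idx] = next; stack.push_back(idx); }
      }
    }
  }
  return lab;
}
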