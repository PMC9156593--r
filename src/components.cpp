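#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 3D connected-component labelling by iterative flood fill.
// mask: logical vector with 3D dim; connectivity: 6, 18 or 26.
// Returns integer array of labels (0 = background), labelled in first-voxel
// (column-major) order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  if (d.size() != 3) stop("mask must be a 3D array");
  int X = d[0], Y = d[1], Z = d[2];
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        int manh = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (manh == 0) continue;
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }

  IntegerVector lab(static_cast<R_xlen_t>(X) * Y * Z);
  lab.attr("dim") = d;
  int next = 0;
  std::vector<R_xlen_t> stack;

  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int cx = cur % X, cy = (cur / X) % Y, cz = cur / (static_cast<R_xlen_t>(X) * Y);
      for (size_t k = 0; k < dx.size(); ++k) {
        int nx = cx + dx[k], ny = cy + dy[k], nz = cz + dz[k];
        if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
        R_xlen_t ni = nx + static_cast<R_xlen_t>(X) * (ny + static_cast<R_xlen_t>(Y) * nz);
        if (mask[ni] && lab[ni] == 0) {
          lab[ni] = next;
          stack.push_back(ni);
        }
      }
    }
  }
  return lab;
}
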