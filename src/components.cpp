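#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label maximal connected components of a 3D logical array under 6-, 18-
// or 26-connectivity (face; face+edge; face+edge+corner adjacency).
// Returns an integer array of the same shape: 0 outside the foreground,
// component ids 1..n_components inside (ids ordered by first-visited
// voxel in column-major order).
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dims,
                               int connectivity) {
  if (dims.size() != 3) stop("'dims' must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // neighbour offsets
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        int m = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2))
          continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start]) continue;
    ++next;
    labels[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      for (size_t k = 0; k < dx.size(); ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[w] && !labels[w]) {
          labels[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  return labels;
}
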