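#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a binary mask (logical/integer matrix).
// connectivity: 4 or 8. Returns integer matrix, 0 = background,
// components numbered 1..n in raster (column-major) discovery order.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dx8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nd = (connectivity == 8) ? 8 : 4;
  int nl = 0;
  std::queue<int> q;
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      if (!mask(y, x) || lab(y, x)) continue;
      ++nl;
      lab(y, x) = nl;
      q.push(y + x * H);
      while (!q.empty()) {
        int p = q.front(); q.pop();
        int cy = p % H, cx = p / H;
        for (int k = 0; k < nd; ++k) {
          int ny = cy + dy8[k], nx = cx + dx8[k];
          if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
          if (mask(ny, nx) && !lab(ny, nx)) { lab(ny, nx) = nl; q.push(ny + nx * H); }
        }
      }
    }
  return lab;
}
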