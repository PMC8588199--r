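#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// SLIC superpixel clustering on a CIELab image.
// L, A, B: H x W matrices. K: requested superpixel count.
// m: compactness (Lab units). iters: k-means passes.
// Returns H x W integer label matrix, labels 0..K'-1, each label 4-connected.
// [[Rcpp::export(name = ".slic_cpp")]]
IntegerMatrix slic_cpp(NumericMatrix L, NumericMatrix A, NumericMatrix B,
                       int K, double m, int iters) {
  const int H = L.nrow(), W = L.ncol();
  const double N = (double)H * W;
  const double S = std::sqrt(N / K);
  const int Si = std::max(1, (int)std::lround(S));

  // grid-initialize cluster centers
  std::vector<double> cy, cx, cl, ca, cb;
  for (double y = S / 2.0; y < H; y += S)
    for (double x = S / 2.0; x < W; x += S) {
      int iy = std::min(H - 1, (int)y), ix = std::min(W - 1, (int)x);
      cy.push_back(iy); cx.push_back(ix);
      cl.push_back(L(iy, ix)); ca.push_back(A(iy, ix)); cb.push_back(B(iy, ix));
    }
  int nc = (int)cy.size();
  std::vector<int> lab(H * W, -1);
  std::vector<double> dist(H * W);
  const double invS2 = (m / S) * (m / S);

  for (int it = 0; it < iters; ++it) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int c = 0; c < nc; ++c) {
      int y0 = std::max(0, (int)cy[c] - 2 * Si), y1 = std::min(H - 1, (int)cy[c] + 2 * Si);
      int x0 = std::max(0, (int)cx[c] - 2 * Si), x1 = std::min(W - 1, (int)cx[c] + 2 * Si);
      for (int x = x0; x <= x1; ++x) {
        for (int y = y0; y <= y1; ++y) {
          double dl = L(y, x) - cl[c], da = A(y, x) - ca[c], db = B(y, x) - cb[c];
          double dy = y - cy[c], dx = x - cx[c];
          double d = dl * dl + da * da + db * db + invS2 * (dy * dy + dx * dx);
          int p = y + x * H;
          if (d < dist[p]) { dist[p] = d; lab[p] = c; }
        }
      }
    }
    // update centers
    std::vector<double> sy(nc, 0), sx(nc, 0), sl(nc, 0), sa(nc, 0), sb(nc, 0), cnt(nc, 0);
    for (int x = 0; x < W; ++x)
      for (int y = 0; y < H; ++y) {
        int c = lab[y + x * H];
        if (c < 0) continue;
        sy[c] += y; sx[c] += x; sl[c] += L(y, x); sa[c] += A(y, x); sb[c] += B(y, x);
        cnt[c] += 1;
      }
    for (int c = 0; c < nc; ++c)
      if (cnt[c] > 0) {
        cy[c] = sy[c] / cnt[c]; cx[c] = sx[c] / cnt[c];
        cl[c] = sl[c] / cnt[c]; ca[c] = sa[c] / cnt[c]; cb[c] = sb[c] / cnt[c];
      }
  }

  // enforce connectivity: BFS components; orphans smaller than S^2/4
  // are merged into an adjacent already-accepted segment
  std::vector<int> out(H * W, -1);
  const int minsz = std::max(1, (Si * Si) / 4);
  int nl = 0;
  const int dy4[4] = {-1, 1, 0, 0}, dx4[4] = {0, 0, -1, 1};
  std::vector<int> comp; comp.reserve(H * W / 4);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      int p = y + x * H;
      if (out[p] >= 0) continue;
      comp.clear();
      int adj = -1;  // neighbouring accepted label
      std::queue<int> q; q.push(p); out[p] = nl; comp.push_back(p);
      while (!q.empty()) {
        int cp = q.front(); q.pop();
        int cyp = cp % H, cxp = cp / H;
        for (int k = 0; k < 4; ++k) {
          int ny = cyp + dy4[k], nx = cxp + dx4[k];
          if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
          int np = ny + nx * H;
          if (out[np] >= 0 && out[np] != nl) adj = out[np];
          if (out[np] < 0 && lab[np] == lab[p]) {
            out[np] = nl; comp.push_back(np); q.push(np);
          }
        }
      }
      if ((int)comp.size() < minsz && adj >= 0) {
        for (int cp : comp) out[cp] = adj;
      } else nl++;
    }

  IntegerMatrix res(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) res(y, x) = out[y + x * H];
  return res;
}
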