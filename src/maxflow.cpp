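#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cstdint>
#include <climits>
using namespace Rcpp;

// Boykov-Kolmogorov max-flow / min-cut for s-t segmentation energies.
//
// n      : number of non-terminal nodes (1..n in the R interface)
// src_cap: length-n capacities s -> i (cost of labelling i "sink")
// snk_cap: length-n capacities i -> t (cost of labelling i "source")
// from,to: m-length arc endpoints (1-based, symmetric capacity cap each way)
// cap    : m-length nonnegative capacities
//
// Returns integer vector: 1 if node is on the SOURCE side of the min cut.
//
// Implementation follows the published BK search-tree algorithm
// (grow / augment / adopt) with terminal capacities folded into a
// per-node residual tr_cap (positive: residual edge from s, negative: to t).

namespace {

struct BKGraph {
  int n;
  std::vector<int> first;          // head of arc list per node (-1 none)
  std::vector<int> nxt, head;      // arc -> next arc of same tail, arc -> head node
  std::vector<double> rcap;        // residual capacity per directed arc
  std::vector<double> tr;          // terminal residual (s if >0, t if <0)
  std::vector<int> parent;         // arc into node from its tree parent (-2 terminal, -1 none)
  std::vector<uint8_t> tree;       // 0 free, 1 S-tree, 2 T-tree
  std::vector<int> ts;             // timestamp of dist validity
  std::vector<int> dist;           // distance to terminal
  std::deque<int> active;
  std::deque<int> orphans;
  int time_cnt = 0;
  double flow = 0;

  void add_arc(int u, int v, double c_uv, double c_vu) {
    int a = (int)head.size();
    head.push_back(v); rcap.push_back(c_uv); nxt.push_back(first[u]); first[u] = a;
    head.push_back(u); rcap.push_back(c_vu); nxt.push_back(first[v]); first[v] = a + 1;
  }

  void init_trees() {
    for (int i = 0; i < n; ++i) {
      if (tr[i] > 0)      { tree[i] = 1; parent[i] = -2; dist[i] = 1; ts[i] = 0; active.push_back(i); }
      else if (tr[i] < 0) { tree[i] = 2; parent[i] = -2; dist[i] = 1; ts[i] = 0; active.push_back(i); }
      else { tree[i] = 0; parent[i] = -1; }
    }
  }

  // returns boundary arc a (from S-side tail to T-side head) or -1
  int grow() {
    while (!active.empty()) {
      int p = active.front();
      if (tree[p] == 0) { active.pop_front(); continue; }
      for (int a = first[p]; a != -1; a = nxt[a]) {
        // arcs usable from p in its tree direction
        double c = (tree[p] == 1) ? rcap[a] : rcap[a ^ 1];
        if (c <= 0) continue;
        int q = head[a];
        if (tree[q] == 0) {
          tree[q] = tree[p];
          parent[q] = a ^ 1;  // arc from q to its parent p
          ts[q] = ts[p]; dist[q] = dist[p] + 1;
          active.push_back(q);
        } else if (tree[q] != tree[p]) {
          return (tree[p] == 1) ? a : (a ^ 1);
        }
      }
      active.pop_front();
    }
    return -1;
  }

  void augment(int a) {
    // path: s ... u -(a)-> v ... t with u in S-tree, v in T-tree.
    // For an S-tree node q, flow runs parent -> q, i.e. along arc parent[q]^1;
    // for a T-tree node q it runs q -> parent along arc parent[q].
    int u = head[a ^ 1], v = head[a];
    std::vector<int> snodes, tnodes;  // path nodes below each root
    int p = u;
    while (parent[p] != -2) { snodes.push_back(p); p = head[parent[p]]; }
    int sroot = p;
    p = v;
    while (parent[p] != -2) { tnodes.push_back(p); p = head[parent[p]]; }
    int troot = p;

    double b = rcap[a];
    b = std::min(b, tr[sroot]);
    b = std::min(b, -tr[troot]);
    for (int q : snodes) b = std::min(b, rcap[parent[q] ^ 1]);
    for (int q : tnodes) b = std::min(b, rcap[parent[q]]);

    rcap[a] -= b; rcap[a ^ 1] += b;
    for (int q : snodes) {
      int pa = parent[q];
      rcap[pa ^ 1] -= b; rcap[pa] += b;
      if (rcap[pa ^ 1] <= 0) { parent[q] = -1; orphans.push_back(q); }
    }
    tr[sroot] -= b;
    if (tr[sroot] <= 0) { parent[sroot] = -1; orphans.push_back(sroot); }
    for (int q : tnodes) {
      int pa = parent[q];
      rcap[pa] -= b; rcap[pa ^ 1] += b;
      if (rcap[pa] <= 0) { parent[q] = -1; orphans.push_back(q); }
    }
    tr[troot] += b;
    if (tr[troot] >= 0) { parent[troot] = -1; orphans.push_back(troot); }
    flow += b;
  }

  bool valid_origin(int p) {
    // walk to root checking timestamps; mark path with current time
    int d = 0;
    int q = p;
    while (true) {
      if (ts[q] == time_cnt) { d += dist[q]; break; }
      int pa = parent[q];
      if (pa == -2) { d += 1; ts[q] = time_cnt; dist[q] = 1; break; }
      if (pa == -1) return false;
      ++d;
      q = head[pa];
    }
    // second pass to set dist along the walked prefix
    int dd = d;
    for (int r = p; ts[r] != time_cnt; r = head[parent[r]]) { ts[r] = time_cnt; dist[r] = dd--; }
    return true;
  }

  void adopt() {
    while (!orphans.empty()) {
      int p = orphans.front(); orphans.pop_front();
      uint8_t tp = tree[p];
      ++time_cnt;
      // find new parent
      int best = -1, bestd = INT_MAX;
      for (int a = first[p]; a != -1; a = nxt[a]) {
        int q = head[a];
        if (tree[q] != tp) continue;
        double c = (tp == 1) ? rcap[a ^ 1] : rcap[a];  // capacity q->p in tree direction
        if (c <= 0) continue;
        if (!valid_origin(q)) continue;
        if (dist[q] + 1 < bestd) { bestd = dist[q] + 1; best = a; }
      }
      if (best != -1) {
        parent[p] = best; ts[p] = time_cnt; dist[p] = bestd;
      } else {
        // p becomes free; children become orphans, neighbours activated
        for (int a = first[p]; a != -1; a = nxt[a]) {
          int q = head[a];
          if (tree[q] != tp) continue;
          double c = (tp == 1) ? rcap[a ^ 1] : rcap[a];
          if (c > 0) active.push_back(q);
          if (parent[q] >= 0 && head[parent[q]] == p) { parent[q] = -1; orphans.push_back(q); }
        }
        tree[p] = 0; parent[p] = -1;
      }
    }
  }

  void run() {
    init_trees();
    while (true) {
      int a = grow();
      if (a == -1) break;
      augment(a);
      adopt();
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".bk_maxflow_cpp")]]
List bk_maxflow_cpp(int n, NumericVector src_cap, NumericVector snk_cap,
                    IntegerVector from, IntegerVector to, NumericVector cap) {
  BKGraph g;
  g.n = n;
  g.first.assign(n, -1);
  g.tr.resize(n);
  g.parent.assign(n, -1);
  g.tree.assign(n, 0);
  g.ts.assign(n, -1);
  g.dist.assign(n, 0);
  size_t m = from.size();
  g.head.reserve(2 * m); g.rcap.reserve(2 * m); g.nxt.reserve(2 * m);
  double base = 0;
  for (int i = 0; i < n; ++i) {
    double s = src_cap[i], t = snk_cap[i];
    base += std::min(s, t);
    g.tr[i] = s - t;
  }
  for (size_t e = 0; e < m; ++e)
    g.add_arc(from[e] - 1, to[e] - 1, cap[e], cap[e]);
  g.run();
  IntegerVector side(n);
  for (int i = 0; i < n; ++i) side[i] = (g.tree[i] == 1) ? 1 : 0;
  return List::create(_["source_side"] = side, _["flow"] = g.flow + base);
}
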