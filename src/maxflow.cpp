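// Boykov-Kolmogorov max-flow / min-cut on an 8-connected pixel grid.
// Used as the energy-minimisation core of the GrabCut segmentation step.
//
// Nodes are pixels of an H x W window, column-major (p = x*H + y).
// Terminal capacities: src_cap (source->pixel), snk_cap (pixel->sink).
// Neighbour capacities are symmetric, given per pixel for the four
// directions down (y+1), right (x+1), down-right, up-right; entries whose
// neighbour falls outside the grid are ignored.
// Returns a logical vector: TRUE = pixel on the source (foreground) side.

#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>
using namespace Rcpp;

namespace {

const int P_NONE = -1, P_TERMINAL = -2, P_ORPHAN = -3;

struct BKGraph {
  int n;
  std::vector<int> first, nxt, head;
  std::vector<double> rcap;
  std::vector<double> tr;          // >0: residual source->v, <0: residual v->sink
  std::vector<signed char> tree;   // 0 free, 1 source, 2 sink
  std::vector<int> parent;         // arc index v->parent, or P_*
  std::vector<long> tstamp;
  std::vector<int> dist;
  long TIME = 0;
  std::deque<int> active;
  std::deque<int> orphans;

  explicit BKGraph(int n_) : n(n_), first(n_, -1), tr(n_, 0.0),
    tree(n_, 0), parent(n_, P_NONE), tstamp(n_, -1), dist(n_, 0) {}

  void add_edge(int u, int v, double cap) {
    int a = (int)head.size();
    head.push_back(v); nxt.push_back(first[u]); first[u] = a; rcap.push_back(cap);
    head.push_back(u); nxt.push_back(first[v]); first[v] = a + 1; rcap.push_back(cap);
  }

  void set_active(int v) { active.push_back(v); }

  // verify v's parent chain reaches a terminal; memoise with TIME stamps
  bool origin_ok(int v) {
    std::vector<int> chain;
    int base, cur = v;
    while (true) {
      if (tstamp[cur] == TIME) { base = dist[cur]; break; }
      int p = parent[cur];
      if (p == P_TERMINAL) { tstamp[cur] = TIME; dist[cur] = 0; base = 0; break; }
      if (p == P_NONE || p == P_ORPHAN) return false;
      chain.push_back(cur);
      cur = head[p];
    }
    for (int i = (int)chain.size() - 1; i >= 0; --i) {
      ++base;
      tstamp[chain[i]] = TIME;
      dist[chain[i]] = base;
    }
    return true;
  }

  void augment(int s_end, int t_end, int a_mid) {
    // bottleneck
    double bn = rcap[a_mid];
    for (int v = s_end; parent[v] != P_TERMINAL; v = head[parent[v]])
      bn = std::min(bn, rcap[parent[v] ^ 1]);
    { int r = s_end; while (parent[r] != P_TERMINAL) r = head[parent[r]];
      bn = std::min(bn, tr[r]); }
    for (int v = t_end; parent[v] != P_TERMINAL; v = head[parent[v]])
      bn = std::min(bn, rcap[parent[v]]);
    { int r = t_end; while (parent[r] != P_TERMINAL) r = head[parent[r]];
      bn = std::min(bn, -tr[r]); }

    // push (roots located before any parent pointers are overwritten)
    int s_root = s_end; while (parent[s_root] != P_TERMINAL) s_root = head[parent[s_root]];
    int t_root = t_end; while (parent[t_root] != P_TERMINAL) t_root = head[parent[t_root]];
    rcap[a_mid] -= bn; rcap[a_mid ^ 1] += bn;
    for (int v = s_end; v != s_root; ) {
      int a = parent[v];
      int nextv = head[a];
      rcap[a ^ 1] -= bn; rcap[a] += bn;
      if (rcap[a ^ 1] <= 0) { parent[v] = P_ORPHAN; orphans.push_back(v); }
      v = nextv;
    }
    tr[s_root] -= bn;
    if (tr[s_root] <= 0) { parent[s_root] = P_ORPHAN; orphans.push_back(s_root); }
    for (int v = t_end; v != t_root; ) {
      int a = parent[v];
      int nextv = head[a];
      rcap[a] -= bn; rcap[a ^ 1] += bn;
      if (rcap[a] <= 0) { parent[v] = P_ORPHAN; orphans.push_back(v); }
      v = nextv;
    }
    tr[t_root] += bn;
    if (tr[t_root] >= 0) { parent[t_root] = P_ORPHAN; orphans.push_back(t_root); }
  }

  void adopt(int u) {
    signed char Tt = tree[u];
    int best = P_NONE;
    for (int a = first[u]; a != -1; a = nxt[a]) {
      int w = head[a];
      if (tree[w] != Tt) continue;
      double c = (Tt == 1) ? rcap[a ^ 1] : rcap[a];
      if (c <= 0) continue;
      if (origin_ok(w)) { best = a; break; }
    }
    if (best != P_NONE) {
      parent[u] = best;
      tstamp[u] = TIME; dist[u] = dist[head[best]] + 1;
      set_active(u);  // may still have unexplored free neighbours
      return;
    }
    // no parent found: free the node, orphan children, reactivate neighbours
    for (int a = first[u]; a != -1; a = nxt[a]) {
      int w = head[a];
      if (tree[w] != Tt) continue;
      double c = (Tt == 1) ? rcap[a ^ 1] : rcap[a];
      if (c > 0) set_active(w);
      int pw = parent[w];
      if (pw >= 0 && head[pw] == u) { parent[w] = P_ORPHAN; orphans.push_back(w); }
    }
    tree[u] = 0; parent[u] = P_NONE;
  }

  void run() {
    for (int v = 0; v < n; ++v) {
      if (tr[v] > 0) { tree[v] = 1; parent[v] = P_TERMINAL; set_active(v); }
      else if (tr[v] < 0) { tree[v] = 2; parent[v] = P_TERMINAL; set_active(v); }
    }
    while (!active.empty()) {
      int v = active.front(); active.pop_front();
      if (tree[v] == 0) continue;
      signed char Tv = tree[v];
      int a = first[v];
      while (a != -1) {
        double c = (Tv == 1) ? rcap[a] : rcap[a ^ 1];
        if (c <= 0) { a = nxt[a]; continue; }
        int u = head[a];
        if (tree[u] == 0) {
          tree[u] = Tv;
          parent[u] = a ^ 1;
          tstamp[u] = tstamp[v]; dist[u] = dist[v] + 1;
          set_active(u);
          a = nxt[a];
        } else if (tree[u] != Tv) {
          // augmenting path found through (v,u)
          ++TIME;
          if (Tv == 1) augment(v, u, a);
          else augment(u, v, a ^ 1);
          while (!orphans.empty()) {
            int o = orphans.front(); orphans.pop_front();
            // fresh TIME per adoption event: stamps made while other orphans
            // are pending must not vouch for chains through them
            ++TIME;
            if (parent[o] == P_ORPHAN) adopt(o);
          }
          if (tree[v] != Tv) break;  // v freed or switched during adoption
          // stay on the same arc: u may now be free and adoptable
        } else {
          a = nxt[a];
        }
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".grid_mincut_cpp")]]
LogicalVector grid_mincut_cpp(int H, int W,
                              NumericVector src_cap, NumericVector snk_cap,
                              NumericVector cap_down, NumericVector cap_right,
                              NumericVector cap_dr, NumericVector cap_ur) {
  int N = H * W;
  BKGraph g(N);
  for (int p = 0; p < N; ++p) g.tr[p] = src_cap[p] - snk_cap[p];
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      int p = x * H + y;
      if (y + 1 < H && cap_down[p] > 0) g.add_edge(p, p + 1, cap_down[p]);
      if (x + 1 < W && cap_right[p] > 0) g.add_edge(p, p + H, cap_right[p]);
      if (y + 1 < H && x + 1 < W && cap_dr[p] > 0) g.add_edge(p, p + H + 1, cap_dr[p]);
      if (y - 1 >= 0 && x + 1 < W && cap_ur[p] > 0) g.add_edge(p, p + H - 1, cap_ur[p]);
    }
  }
  g.run();
  LogicalVector out(N);
  for (int p = 0; p < N; ++p) out[p] = (g.tree[p] == 1);
  return out;
}
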