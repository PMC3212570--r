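// Exact min-cut on a 4-connected pixel grid with terminal (unary) arcs,
// via Dinic's max-flow. Capacities are quantized onto a fine integer grid
// (relative step 1e-8 of the largest capacity) so augmentation terminates;
// the returned labeling is the exact optimum of the quantized energy.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Dinic {
  int n;                       // total vertices incl. s, t
  std::vector<int> to, nxt, first;
  std::vector<int64_t> cap;
  std::vector<int> level, iter;

  explicit Dinic(int n_) : n(n_), first(n_, -1), level(n_), iter(n_) {}

  void add_edge(int u, int v, int64_t c_fwd, int64_t c_rev) {
    to.push_back(v); cap.push_back(c_fwd); nxt.push_back(first[u]);
    first[u] = (int)to.size() - 1;
    to.push_back(u); cap.push_back(c_rev); nxt.push_back(first[v]);
    first[v] = (int)to.size() - 1;
  }

  bool bfs(int s, int t) {
    std::fill(level.begin(), level.end(), -1);
    std::queue<int> q;
    level[s] = 0; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int e = first[u]; e != -1; e = nxt[e]) {
        if (cap[e] > 0 && level[to[e]] < 0) {
          level[to[e]] = level[u] + 1;
          q.push(to[e]);
        }
      }
    }
    return level[t] >= 0;
  }

  // iterative blocking flow (explicit path stack; no recursion)
  void max_flow(int s, int t) {
    while (bfs(s, t)) {
      for (int i = 0; i < n; ++i) iter[i] = first[i];
      std::vector<int> path;
      int u = s;
      while (true) {
        if (u == t) {
          int64_t f = INT64_MAX;
          for (int e : path) f = std::min(f, cap[e]);
          for (int e : path) { cap[e] -= f; cap[e ^ 1] += f; }
          path.clear(); u = s; continue;
        }
        int e = iter[u];
        while (e != -1 && !(cap[e] > 0 && level[to[e]] == level[u] + 1))
          e = nxt[e];
        iter[u] = e;
        if (e == -1) {
          if (u == s) break;       // blocking flow complete
          level[u] = -1;           // dead end; prune
          int back = path.back(); path.pop_back();
          u = to[back ^ 1];
        } else {
          path.push_back(e);
          u = to[e];
        }
      }
    }
  }

  // source-reachable set in the residual graph = source side of a min cut
  std::vector<char> source_side(int s) {
    std::vector<char> vis(n, 0);
    std::queue<int> q;
    vis[s] = 1; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int e = first[u]; e != -1; e = nxt[e]) {
        if (cap[e] > 0 && !vis[to[e]]) { vis[to[e]] = 1; q.push(to[e]); }
      }
    }
    return vis;
  }
};

} // namespace

// [[Rcpp::export(name = ".grid_mincut_cpp")]]
LogicalMatrix grid_mincut_cpp(NumericMatrix cost_cell, NumericMatrix cost_bg,
                              NumericMatrix w_right, NumericMatrix w_down) {
  const int h = cost_cell.nrow(), w = cost_cell.ncol();
  const int n = h * w, s = n, t = n + 1;

  double max_cap = 0;
  for (int i = 0; i < n; ++i) {
    max_cap = std::max(max_cap, std::max(cost_cell[i], cost_bg[i]));
  }
  for (int i = 0; i < w_right.length(); ++i) max_cap = std::max(max_cap, w_right[i]);
  for (int i = 0; i < w_down.length(); ++i) max_cap = std::max(max_cap, w_down[i]);
  const double scale = max_cap > 0 ? 1e8 / max_cap : 1.0;
  auto q = [scale](double x) { return (int64_t)std::llround(x * scale); };

  Dinic g(n + 2);
  // column-major pixel ids, matching R's matrix layout
  auto pix = [h](int r, int c) { return c * h + r; };
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      const int i = pix(r, c);
      // s->i cut iff i on sink (background) side; i->t cut iff cellular
      int64_t cb = q(cost_bg(r, c)), cc = q(cost_cell(r, c));
      if (cb > 0) g.add_edge(s, i, cb, 0);
      if (cc > 0) g.add_edge(i, t, cc, 0);
      if (c + 1 < w) {
        int64_t wr = q(w_right(r, c));
        if (wr > 0) g.add_edge(i, pix(r, c + 1), wr, wr);
      }
      if (r + 1 < h) {
        int64_t wd = q(w_down(r, c));
        if (wd > 0) g.add_edge(i, pix(r + 1, c), wd, wd);
      }
    }
  }
  g.max_flow(s, t);
  std::vector<char> src = g.source_side(s);

  LogicalMatrix out(h, w);
  for (int i = 0; i < n; ++i) out[i] = src[i] ? FALSE : TRUE; // sink side = background
  return out;
}
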