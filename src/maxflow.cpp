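#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Dinic max-flow on the two-terminal pixel graph used by the Chan-Vese
// graph cut. Arcs are stored in pairs (arc k and its reverse k^1), so a
// symmetric Potts pair {i, j} is one arc pair with capacity w on both
// sides, and a terminal link is an arc pair with zero reverse capacity.
//
// Returns the canonical minimum cut as 0/1 labels over the n pixel nodes:
// label 1 for nodes reachable from the source in the residual network.

struct DinicGraph {
  int n;
  std::vector<int> to, head, nxt;
  std::vector<double> cap;
  explicit DinicGraph(int nodes) : n(nodes), head(nodes, -1) {}
  void add_pair(int u, int v, double c_uv, double c_vu) {
    to.push_back(v); cap.push_back(c_uv); nxt.push_back(head[u]);
    head[u] = (int)to.size() - 1;
    to.push_back(u); cap.push_back(c_vu); nxt.push_back(head[v]);
    head[v] = (int)to.size() - 1;
  }
};

// [[Rcpp::export(name = ".grid_mincut")]]
IntegerVector grid_mincut(int n_pixels,
                          IntegerVector pair_i, IntegerVector pair_j,
                          NumericVector pair_w,
                          NumericVector cap_source, NumericVector cap_sink) {
  const int n = n_pixels + 2;
  const int s = n_pixels, t = n_pixels + 1;
  DinicGraph g(n);
  double cmax = 0.0;
  for (int i = 0; i < n_pixels; ++i) {
    if (cap_source[i] > 0) { g.add_pair(s, i, cap_source[i], 0.0); cmax = std::max(cmax, cap_source[i]); }
    if (cap_sink[i]   > 0) { g.add_pair(i, t, cap_sink[i], 0.0);   cmax = std::max(cmax, cap_sink[i]); }
  }
  for (int k = 0; k < pair_i.size(); ++k) {
    if (pair_w[k] > 0) {
      g.add_pair(pair_i[k] - 1, pair_j[k] - 1, pair_w[k], pair_w[k]);
      cmax = std::max(cmax, pair_w[k]);
    }
  }
  const double eps = 1e-12 * std::max(cmax, 1.0);

  std::vector<int> level(n), it(n);
  std::queue<int> q;
  auto bfs = [&]() -> bool {
    std::fill(level.begin(), level.end(), -1);
    level[s] = 0;
    q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int e = g.head[u]; e != -1; e = g.nxt[e])
        if (g.cap[e] > eps && level[g.to[e]] < 0) {
          level[g.to[e]] = level[u] + 1;
          q.push(g.to[e]);
        }
    }
    return level[t] >= 0;
  };

  // iterative blocking-flow DFS (explicit stack of arcs on the path)
  std::vector<int> path;
  while (bfs()) {
    for (int u = 0; u < n; ++u) it[u] = g.head[u];
    for (;;) {
      int u = path.empty() ? s : g.to[path.back()];
      if (u == t) {
        double aug = std::numeric_limits<double>::max();
        for (int e : path) aug = std::min(aug, g.cap[e]);
        for (int e : path) { g.cap[e] -= aug; g.cap[e ^ 1] += aug; }
        // retreat to the first saturated arc
        size_t cut = 0;
        for (size_t kk = 0; kk < path.size(); ++kk)
          if (g.cap[path[kk]] <= eps) { cut = kk; break; }
        path.resize(cut);
        continue;
      }
      int &e = it[u];
      while (e != -1 && !(g.cap[e] > eps && level[g.to[e]] == level[u] + 1))
        e = g.nxt[e];
      if (e == -1) {
        if (path.empty()) break;      // blocking flow complete
        level[u] = -1;                // dead end; prune
        path.pop_back();
      } else {
        path.push_back(e);
      }
    }
    path.clear();
  }

  // canonical minimum cut: residual reachability from the source
  IntegerVector labels(n_pixels, 0);
  std::vector<char> seen(n, 0);
  seen[s] = 1;
  q.push(s);
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (int e = g.head[u]; e != -1; e = g.nxt[e])
      if (g.cap[e] > eps && !seen[g.to[e]]) {
        seen[g.to[e]] = 1;
        q.push(g.to[e]);
      }
  }
  for (int i = 0; i < n_pixels; ++i) labels[i] = seen[i];
  return labels;
}
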