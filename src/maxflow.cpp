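// Exact s-t min-cut on a pixel grid via Dinic's max-flow algorithm.
//
// The two-label MRF with Potts pairwise cost reduces to a single min-cut:
// source-side pixels are foreground. Terminal arc capacities are the unary
// costs of the opposite label; neighbour arcs carry the constant cut
// penalty kappa in both directions.

#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

namespace {

struct Dinic {
  struct Arc { int to; double cap; int rev; };
  std::vector<std::vector<Arc>> g;
  std::vector<int> level, iter;
  explicit Dinic(int n) : g(n), level(n), iter(n) {}

  void add_edge(int from, int to, double cap, double rcap = 0.0) {
    g[from].push_back({to, cap, (int)g[to].size()});
    g[to].push_back({from, rcap, (int)g[from].size() - 1});
  }

  bool bfs(int s, int t) {
    std::fill(level.begin(), level.end(), -1);
    std::queue<int> q;
    level[s] = 0; q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (const Arc &a : g[v]) {
        if (a.cap > 1e-12 && level[a.to] < 0) {
          level[a.to] = level[v] + 1;
          q.push(a.to);
        }
      }
    }
    return level[t] >= 0;
  }

  // iterative blocking flow (paths on a pixel grid can be thousands of
  // nodes long; recursion would overflow the stack)
  void blocking_flow(int s, int t) {
    std::vector<std::pair<int, int>> path; // (node, arc index taken)
    int v = s;
    while (true) {
      if (v == t) {
        double f = std::numeric_limits<double>::infinity();
        for (auto &p : path) f = std::min(f, g[p.first][p.second].cap);
        for (auto &p : path) {
          Arc &a = g[p.first][p.second];
          a.cap -= f;
          g[a.to][a.rev].cap += f;
        }
        // retreat to just below the first saturated arc
        size_t cut = 0;
        while (cut < path.size() &&
               g[path[cut].first][path[cut].second].cap > 1e-12) ++cut;
        path.resize(cut);
        v = path.empty() ? s : g[path.back().first][path.back().second].to;
        continue;
      }
      if (iter[v] < (int)g[v].size()) {
        const Arc &a = g[v][iter[v]];
        if (a.cap > 1e-12 && level[v] < level[a.to]) {
          path.push_back({v, iter[v]});
          v = a.to;
        } else {
          ++iter[v];
        }
      } else {
        level[v] = -1; // dead end this phase
        if (v == s) break;
        v = path.back().first;
        path.pop_back();
        ++iter[v];
      }
    }
  }

  void run(int s, int t) {
    while (bfs(s, t)) {
      std::fill(iter.begin(), iter.end(), 0);
      blocking_flow(s, t);
    }
  }

  // source side of the min cut in the residual graph
  std::vector<bool> source_side(int s) {
    std::vector<bool> vis(g.size(), false);
    std::queue<int> q;
    vis[s] = true; q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (const Arc &a : g[v]) {
        if (a.cap > 1e-12 && !vis[a.to]) {
          vis[a.to] = true;
          q.push(a.to);
        }
      }
    }
    return vis;
  }
};

} // namespace

// [[Rcpp::export]]
IntegerMatrix grid_mincut(NumericMatrix cost_bg, NumericMatrix cost_fg,
                          double kappa, int connectivity) {
  const int h = cost_bg.nrow(), w = cost_bg.ncol(), n = h * w;
  const int s = n, t = n + 1;
  Dinic din(n + 2);
  // terminal arcs: cutting (i, t) assigns foreground and pays cost_fg;
  // cutting (s, i) assigns background and pays cost_bg
  for (int i = 0; i < n; ++i) {
    din.add_edge(s, i, cost_bg[i]);
    din.add_edge(i, t, cost_fg[i]);
  }
  if (kappa > 0) {
    for (int c = 0; c < w; ++c) {
      for (int r = 0; r < h; ++r) {
        int i = c * h + r;
        if (r + 1 < h) din.add_edge(i, i + 1, kappa, kappa);
        if (c + 1 < w) din.add_edge(i, i + h, kappa, kappa);
        if (connectivity == 8) {
          if (r + 1 < h && c + 1 < w) din.add_edge(i, i + h + 1, kappa, kappa);
          if (r > 0 && c + 1 < w) din.add_edge(i, i + h - 1, kappa, kappa);
        }
      }
    }
  }
  din.run(s, t);
  std::vector<bool> fg = din.source_side(s);
  IntegerMatrix out(h, w);
  for (int i = 0; i < n; ++i) out[i] = fg[i] ? 1 : 0;
  return out;
}
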