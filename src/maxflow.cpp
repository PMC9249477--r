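#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>

using namespace Rcpp;

// Dinic's blocking-flow max-flow on a directed capacitated graph.
// Nodes are 1-based on the R side.  Every input arc gets a paired
// residual arc of capacity 0; antiparallel input arcs are simply two
// independent arc pairs, which is sufficient for s-t min cut.

namespace {

struct Arc {
  int to;
  double cap;
  int rev;  // index of the reverse arc in graph[to]
};

class Dinic {
public:
  explicit Dinic(int n) : graph_(n), level_(n), iter_(n) {}

  void add_arc(int from, int to, double cap) {
    graph_[from].push_back({to, cap, static_cast<int>(graph_[to].size())});
    graph_[to].push_back({from, 0.0, static_cast<int>(graph_[from].size()) - 1});
  }

  double run(int s, int t) {
    double flow = 0.0;
    while (bfs(s, t)) {
      std::fill(iter_.begin(), iter_.end(), 0);
      double f;
      while ((f = dfs(s, t)) > 0.0) flow += f;
    }
    return flow;
  }

  // After run(): nodes still reachable from s in the residual graph.
  std::vector<bool> source_side(int s) const {
    std::vector<bool> seen(graph_.size(), false);
    std::queue<int> q;
    seen[s] = true;
    q.push(s);
    while (!q.empty()) {
      int u = q.front();
      q.pop();
      for (const Arc &a : graph_[u]) {
        if (a.cap > kEps && !seen[a.to]) {
          seen[a.to] = true;
          q.push(a.to);
        }
      }
    }
    return seen;
  }

private:
  static constexpr double kEps = 1e-10;

  bool bfs(int s, int t) {
    std::fill(level_.begin(), level_.end(), -1);
    std::queue<int> q;
    level_[s] = 0;
    q.push(s);
    while (!q.empty()) {
      int u = q.front();
      q.pop();
      for (const Arc &a : graph_[u]) {
        if (a.cap > kEps && level_[a.to] < 0) {
          level_[a.to] = level_[u] + 1;
          q.push(a.to);
        }
      }
    }
    return level_[t] >= 0;
  }

  // Iterative DFS sending one augmenting path per call (grid graphs can
  // be deep, so no recursion).
  double dfs(int s, int t) {
    std::vector<int> path_node{s};
    std::vector<int> path_arc;
    while (!path_node.empty()) {
      int u = path_node.back();
      if (u == t) {
        double f = std::numeric_limits<double>::infinity();
        for (size_t k = 0; k < path_arc.size(); ++k)
          f = std::min(f, graph_[path_node[k]][path_arc[k]].cap);
        for (size_t k = 0; k < path_arc.size(); ++k) {
          Arc &a = graph_[path_node[k]][path_arc[k]];
          a.cap -= f;
          graph_[a.to][a.rev].cap += f;
        }
        return f;
      }
      bool advanced = false;
      for (int &i = iter_[u]; i < static_cast<int>(graph_[u].size()); ++i) {
        const Arc &a = graph_[u][i];
        if (a.cap > kEps && level_[a.to] == level_[u] + 1) {
          path_arc.push_back(i);
          path_node.push_back(a.to);
          advanced = true;
          break;
        }
      }
      if (!advanced) {
        level_[u] = -1;  // dead end, prune
        path_node.pop_back();
        if (!path_arc.empty()) path_arc.pop_back();
      }
    }
    return 0.0;
  }

  std::vector<std::vector<Arc>> graph_;
  std::vector<int> level_;
  std::vector<int> iter_;
};

}  // namespace

// [[Rcpp::export]]
List maxflow_dinic(int n_nodes, IntegerVector from, IntegerVector to,
                   NumericVector cap, int source, int sink) {
  if (from.size() != to.size() || from.size() != cap.size())
    stop("edge vectors must have equal length");
  Dinic d(n_nodes);
  for (R_xlen_t i = 0; i < from.size(); ++i) {
    if (from[i] < 1 || from[i] > n_nodes || to[i] < 1 || to[i] > n_nodes)
      stop("edge endpoint out of range");
    if (cap[i] < 0 || !R_finite(cap[i])) stop("capacities must be finite and non-negative");
    d.add_arc(from[i] - 1, to[i] - 1, cap[i]);
  }
  double flow = d.run(source - 1, sink - 1);
  std::vector<bool> side = d.source_side(source - 1);
  LogicalVector src(n_nodes);
  for (int i = 0; i < n_nodes; ++i) src[i] = side[i];
  return List::create(_["flow"] = flow, _["source_side"] = src);
}
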