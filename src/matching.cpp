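// Structural-controllability backend: maximum matching on the bipartite
// split of a directed network (each node v gives an out-copy v+ and an
// in-copy v-; arc u->v gives bipartite edge (u+, v-)). Driver nodes are the
// nodes whose in-copy is left unmatched by a maximum matching; the matching
// is computed with Kuhn's augmenting-path algorithm whose node visitation
// order is a caller-supplied permutation, so different permutations can
// realize different maximum matchings while the size stays maximal.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

// Kuhn's algorithm. adj[u] lists the in-copies reachable from out-copy u.
// Left nodes are processed in `order`; each adjacency list is pre-sorted by
// the position of the neighbour in `order` so solution content (not size)
// depends on the permutation. Returns match_in: for each in-copy, the
// matched out-copy or -1.
struct Kuhn {
  int n;
  const std::vector<std::vector<int>>& adj;
  std::vector<int> match_in;
  std::vector<char> visited;

  Kuhn(int n_, const std::vector<std::vector<int>>& adj_)
      : n(n_), adj(adj_), match_in(n_, -1), visited(n_, 0) {}

  bool try_augment(int u) {
    for (int v : adj[u]) {
      if (!visited[v]) {
        visited[v] = 1;
        if (match_in[v] == -1 || try_augment(match_in[v])) {
          match_in[v] = u;
          return true;
        }
      }
    }
    return false;
  }

  int run(const std::vector<int>& order) {
    int size = 0;
    for (int u : order) {
      std::fill(visited.begin(), visited.end(), 0);
      if (try_augment(u)) ++size;
    }
    return size;
  }
};

std::vector<std::vector<int>> build_adj(int n, const IntegerVector& from,
                                        const IntegerVector& to) {
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < from.size(); ++i) adj[from[i]].push_back(to[i]);
  return adj;
}

// re-sort each adjacency list by position of the target in `order`
void order_adj(std::vector<std::vector<int>>& adj,
               const std::vector<int>& order) {
  int n = (int)adj.size();
  std::vector<int> pos(n);
  for (int i = 0; i < n; ++i) pos[order[i]] = i;
  for (auto& lst : adj)
    std::sort(lst.begin(), lst.end(),
              [&](int a, int b) { return pos[a] < pos[b]; });
}

// Exact maximum matching by subset DP over the in-copies (independent
// algorithm, used only as a verification oracle; n <= ~20 in-copies).
int dp_max_matching(int n, const std::vector<std::vector<int>>& adj) {
  std::vector<uint32_t> nbr(n, 0);
  for (int u = 0; u < n; ++u)
    for (int v : adj[u]) nbr[u] |= (uint32_t(1) << v);
  size_t states = size_t(1) << n;
  // f[mask] = max matching using left nodes u..n-1, rights in mask used
  std::vector<int8_t> cur(states, 0), nxt(states, 0);
  for (int u = n - 1; u >= 0; --u) {
    std::swap(cur, nxt);
    for (size_t mask = 0; mask < states; ++mask) {
      int best = nxt[mask];
      uint32_t avail = nbr[u] & ~uint32_t(mask);
      while (avail) {
        uint32_t bit = avail & (~avail + 1);
        int cand = 1 + nxt[mask | bit];
        if (cand > best) best = cand;
        avail ^= bit;
      }
      cur[mask] = (int8_t)best;
    }
  }
  return cur[0];
}

// xorshift32 PRNG: cheap, deterministic, independent of R's RNG (only used
// to draw node permutations inside the exhaustive self-check)
struct XorShift {
  uint32_t s;
  explicit XorShift(uint32_t seed) : s(seed ? seed : 0x9e3779b9u) {}
  uint32_t next() {
    s ^= s << 13; s ^= s >> 17; s ^= s << 5;
    return s;
  }
  // uniform integer in [0, k)
  int below(int k) { return (int)(next() % (uint32_t)k); }
  void shuffle(std::vector<int>& v) {
    for (int i = (int)v.size() - 1; i > 0; --i)
      std::swap(v[i], v[(int)(next() % (uint32_t)(i + 1))]);
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_kuhn_match(int n_nodes, IntegerVector from, IntegerVector to,
                    IntegerVector node_order) {
  if (node_order.size() != n_nodes)
    stop("node_order must be a permutation of all nodes");
  std::vector<int> order(node_order.begin(), node_order.end());
  auto adj = build_adj(n_nodes, from, to);
  order_adj(adj, order);
  Kuhn k(n_nodes, adj);
  int size = k.run(order);
  IntegerVector match_in(n_nodes);
  for (int v = 0; v < n_nodes; ++v) match_in[v] = k.match_in[v];
  return List::create(_["matching_size"] = size, _["match_in"] = match_in);
}

// [[Rcpp::export]]
int cpp_dp_matching_size(int n_nodes, IntegerVector from, IntegerVector to) {
  if (n_nodes > 20) stop("DP oracle limited to 20 nodes");
  auto adj = build_adj(n_nodes, from, to);
  return dp_max_matching(n_nodes, adj);
}

// Exhaustively enumerate every simple digraph (no self-loops) on
// 1..n_max labelled nodes; for each graph run Kuhn under n_orders random
// node permutations and compare every run against the DP oracle and the
// driver-count rule |drivers| = max(N - matching_size, 1).
// [[Rcpp::export]]
List cpp_matching_exhaustive_check(int n_max, int n_orders, int seed) {
  if (n_max > 5) stop("exhaustive check limited to 5 nodes");
  XorShift rng((uint32_t)seed);
  long long n_graphs = 0, order_mismatch = 0, driver_rule_violations = 0;
  for (int n = 1; n <= n_max; ++n) {
    // enumerate arcs (u, v), u != v
    std::vector<std::pair<int, int>> arcs;
    for (int u = 0; u < n; ++u)
      for (int v = 0; v < n; ++v)
        if (u != v) arcs.push_back({u, v});
    int n_arcs = (int)arcs.size();
    std::vector<int> order(n);
    for (long long mask = 0; mask < (1LL << n_arcs); ++mask) {
      ++n_graphs;
      std::vector<std::vector<int>> adj(n);
      int n_edges = 0;
      for (int a = 0; a < n_arcs; ++a)
        if (mask & (1LL << a)) {
          adj[arcs[a].first].push_back(arcs[a].second);
          ++n_edges;
        }
      int oracle = dp_max_matching(n, adj);
      for (int t = 0; t < n_orders; ++t) {
        for (int i = 0; i < n; ++i) order[i] = i;
        rng.shuffle(order);
        auto adj_t = adj;
        order_adj(adj_t, order);
        Kuhn k(n, adj_t);
        int size = k.run(order);
        if (size != oracle) {
          ++order_mismatch;
          continue;
        }
        int unmatched = 0;
        for (int v = 0; v < n; ++v)
          if (k.match_in[v] == -1) ++unmatched;
        int drivers = (unmatched == 0) ? 1 : unmatched; // perfect matching
        if (drivers != std::max(n - size, 1)) ++driver_rule_violations;
      }
    }
  }
  return List::create(_["n_graphs"] = (double)n_graphs,
                      _["order_mismatch"] = (double)order_mismatch,
                      _["driver_rule_violations"] = (double)driver_rule_violations);
}
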