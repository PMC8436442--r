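#include <Rcpp.h>
#include <functional>
#include <map>
using namespace Rcpp;

// All-pairs shortest paths by Floyd-Warshall on a dense distance matrix.
// Input: symmetric edge-distance matrix with 0 diagonal and R_PosInf for
// absent edges.  Small dense networks (<= a few hundred nodes) are the
// target; O(n^3) is fine there and avoids any graph-object overhead.
// [[Rcpp::export(name = ".fw_distances")]]
NumericMatrix fw_distances(NumericMatrix d0) {
  int n = d0.nrow();
  NumericMatrix d(clone(d0));
  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < n; ++i) {
      double dik = d(i, k);
      if (!R_finite(dik)) continue;
      for (int j = 0; j < n; ++j) {
        double alt = dik + d(k, j);
        if (alt < d(i, j)) d(i, j) = alt;
      }
    }
  }
  return d;
}

static double subgraph_efficiency(const NumericMatrix &adj,
                                  const std::vector<int> &nodes) {
  int m = nodes.size();
  if (m < 2) return 0.0;
  std::vector<double> d(m * m);
  for (int a = 0; a < m; ++a) {
    for (int b = 0; b < m; ++b) {
      if (a == b) {
        d[a * m + b] = 0.0;
      } else {
        double w = adj(nodes[a], nodes[b]);
        d[a * m + b] = w > 0 ? 1.0 / w : R_PosInf;
      }
    }
  }
  for (int k = 0; k < m; ++k) {
    for (int a = 0; a < m; ++a) {
      double dak = d[a * m + k];
      if (!R_finite(dak)) continue;
      for (int b = 0; b < m; ++b) {
        double alt = dak + d[k * m + b];
        if (alt < d[a * m + b]) d[a * m + b] = alt;
      }
    }
  }
  double s = 0.0;
  for (int a = 0; a < m; ++a)
    for (int b = 0; b < m; ++b)
      if (a != b && R_finite(d[a * m + b])) s += 1.0 / d[a * m + b];
  return s / (m * (m - 1.0));
}

// Per-node local efficiency: global efficiency of the subgraph induced by
// each node's neighbours (distance = 1/weight), 0 for degree < 2.
// [[Rcpp::export(name = ".local_efficiency_impl")]]
NumericVector local_efficiency_impl(NumericMatrix adj) {
  int n = adj.nrow();
  NumericVector eff(n);
  for (int i = 0; i < n; ++i) {
    std::vector<int> nb;
    for (int j = 0; j < n; ++j)
      if (adj(i, j) > 0) nb.push_back(j);
    eff[i] = subgraph_efficiency(adj, nb);
  }
  return eff;
}

// Largest connected-component size (in edges) of the graph given by an
// edge list over nodes 1..n - union-find, called once per permutation in
// the NBS null loop.
// [[Rcpp::export(name = ".max_component_edges_impl")]]
int max_component_edges_impl(IntegerVector ei, IntegerVector ej, int n) {
  int m = ei.size();
  if (m == 0) return 0;
  std::vector<int> parent(n + 1);
  for (int v = 0; v <= n; ++v) parent[v] = v;
  std::function<int(int)> find = [&](int v) {
    while (parent[v] != v) {
      parent[v] = parent[parent[v]];
      v = parent[v];
    }
    return v;
  };
  for (int e = 0; e < m; ++e) {
    int a = find(ei[e]), b = find(ej[e]);
    if (a != b) parent[a] = b;
  }
  std::map<int, int> edge_count;
  int best = 0;
  for (int e = 0; e < m; ++e) {
    int r = find(ei[e]);
    int c = ++edge_count[r];
    if (c > best) best = c;
  }
  return best;
}
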