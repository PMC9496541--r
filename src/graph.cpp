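#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Disjoint-set with path compression + union by rank.
struct DSU {
  std::vector<int> parent, rank_;
  DSU(int n) : parent(n), rank_(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) ++rank_[a];
    return true;
  }
};

// Kruskal over edges already sorted by (weight, tie-break) on the R side.
// Returns a logical keep-flag per edge; kept edges form the minimum
// spanning forest. Vertex indices are 1-based.
// [[Rcpp::export]]
LogicalVector cpp_kruskal_keep(int n_vertices, IntegerVector ei, IntegerVector ej) {
  const int m = ei.size();
  LogicalVector keep(m);
  DSU dsu(n_vertices);
  for (int e = 0; e < m; ++e)
    keep[e] = dsu.unite(ei[e] - 1, ej[e] - 1);
  return keep;
}

// Prune a spanning forest to maximum vertex degree three by removing, at
// each over-degree vertex, whole incident branches (the component hanging
// off a neighbor when the vertex is cut out). The smallest branch by
// vertex count goes first; ties broken by summed density, then by the
// smallest vertex index in the branch. Returns a keep-flag per vertex.
// [[Rcpp::export]]
LogicalVector cpp_prune_degree3(int n_vertices, IntegerVector ei, IntegerVector ej,
                                NumericVector density) {
  const int m = ei.size();
  std::vector<std::vector<int>> adj(n_vertices);
  for (int e = 0; e < m; ++e) {
    adj[ei[e] - 1].push_back(ej[e] - 1);
    adj[ej[e] - 1].push_back(ei[e] - 1);
  }
  std::vector<bool> alive(n_vertices, true);
  std::vector<int> visit_mark(n_vertices, -1);

  auto alive_degree = [&](int v) {
    int d = 0;
    for (int u : adj[v]) if (alive[u]) ++d;
    return d;
  };

  // branch = component containing `start` after deleting vertex `cut`
  auto branch_stats = [&](int start, int cut, int mark,
                          int &count, double &dsum, int &minid,
                          std::vector<int> &members) {
    count = 0; dsum = 0.0; minid = n_vertices;
    members.clear();
    std::queue<int> q;
    q.push(start);
    visit_mark[start] = mark;
    while (!q.empty()) {
      int v = q.front(); q.pop();
      members.push_back(v);
      ++count; dsum += density[v];
      if (v < minid) minid = v;
      for (int u : adj[v]) {
        if (!alive[u] || u == cut || visit_mark[u] == mark) continue;
        visit_mark[u] = mark;
        q.push(u);
      }
    }
  };

  int mark = 0;
  for (int v = 0; v < n_vertices; ++v) {
    if (!alive[v]) continue;
    while (alive_degree(v) > 3) {
      int best_count = -1, best_minid = -1;
      double best_dsum = 0.0;
      std::vector<int> best_members, members;
      for (int u : adj[v]) {
        if (!alive[u]) continue;
        int count, minid; double dsum;
        branch_stats(u, v, mark++, count, dsum, minid, members);
        bool better = false;
        if (best_count < 0) better = true;
        else if (count != best_count) better = count < best_count;
        else if (dsum != best_dsum) better = dsum < best_dsum;
        else better = minid < best_minid;
        if (better) {
          best_count = count; best_dsum = dsum; best_minid = minid;
          best_members = members;
        }
      }
      for (int u : best_members) alive[u] = false;
    }
  }
  LogicalVector keep(n_vertices);
  for (int v = 0; v < n_vertices; ++v) keep[v] = alive[v];
  return keep;
}

// For each query point, the index of (and distance to) the nearest
// reference point. Brute force; both matrices are n x 3.
// [[Rcpp::export]]
List cpp_nearest(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector dmin(nq);
  for (int i = 0; i < nq; ++i) {
    double best = R_PosInf; int bj = 0;
    const double x = query(i, 0), y = query(i, 1), z = query(i, 2);
    for (int j = 0; j < nr; ++j) {
      const double dx = x - ref(j, 0), dy = y - ref(j, 1), dz = z - ref(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dmin[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["dist"] = dmin);
}
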