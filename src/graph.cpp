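// Graph primitives for subsampled surface meshes: Dijkstra with a
// lexicographic tie-break on equal-cost paths, farthest-point subsampling
// with geodesic Voronoi ownership, and an O(n^3) Hungarian assignment solver.
// All node indices at this interface are 0-based; edges come as CSR arrays.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
#include <cmath>
using namespace Rcpp;

typedef std::pair<double, int> QE;

static std::vector<double> dijkstra_dist(int n, const IntegerVector &ptr,
                                         const IntegerVector &idx,
                                         const NumericVector &w,
                                         const std::vector<int> &src) {
  std::vector<double> dist(n, std::numeric_limits<double>::infinity());
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (size_t k = 0; k < src.size(); ++k) { dist[src[k]] = 0.0; pq.push(QE(0.0, src[k])); }
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    if (top.first > dist[top.second]) continue;
    int u = top.second;
    for (int p = ptr[u]; p < ptr[u + 1]; ++p) {
      int v = idx[p];
      double nd = top.first + w[p];
      if (nd < dist[v]) { dist[v] = nd; pq.push(QE(nd, v)); }
    }
  }
  return dist;
}

// [[Rcpp::export]]
NumericVector dijkstra_dist_cpp(int n, IntegerVector ptr, IntegerVector idx,
                                NumericVector w, IntegerVector src) {
  std::vector<int> s(src.begin(), src.end());
  std::vector<double> d = dijkstra_dist(n, ptr, idx, w, s);
  return NumericVector(d.begin(), d.end());
}

// Lexicographically smallest (by node-id sequence) minimum-cost path.
// Walk forward from src, at each step taking the smallest-id neighbor that
// still lies on some shortest path to dst.
// [[Rcpp::export]]
IntegerVector dijkstra_path_cpp(int n, IntegerVector ptr, IntegerVector idx,
                                NumericVector w, int src, int dst) {
  // clamp weights to a tiny positive floor: zero-weight edges (e.g. free
  // passage through cavity nodes) would otherwise allow zero-cost cycles
  // and stall the lexicographic walk below
  NumericVector wc = clone(w);
  double wmax = 0.0;
  for (int i = 0; i < wc.size(); ++i) if (wc[i] > wmax) wmax = wc[i];
  // the floor must exceed the tie tolerance below, so distances strictly
  // increase along the walk and revisits are impossible
  double eps_w = (wmax > 0 ? wmax : 1.0) * 1e-6;
  for (int i = 0; i < wc.size(); ++i) if (wc[i] < eps_w) wc[i] = eps_w;
  NumericVector &w_ = wc;
  std::vector<int> s1(1, src), s2(1, dst);
  std::vector<double> dsrc = dijkstra_dist(n, ptr, idx, w_, s1);
  std::vector<double> ddst = dijkstra_dist(n, ptr, idx, w_, s2);
  double total = dsrc[dst];
  if (!std::isfinite(total)) return IntegerVector(0); // no path
  const double tol = 1e-9 * (1.0 + std::fabs(total));
  std::vector<int> path;
  path.push_back(src);
  int u = src;
  while (u != dst) {
    if ((int)path.size() > n) stop("internal: shortest-path walk cycled");
    int best = -1;
    for (int p = ptr[u]; p < ptr[u + 1]; ++p) {
      int v = idx[p];
      if (std::fabs(dsrc[u] + w_[p] + ddst[v] - total) <= tol &&
          std::fabs(dsrc[u] + w_[p] - dsrc[v]) <= tol) {
        if (best < 0 || v < best) best = v;
      }
    }
    if (best < 0) stop("internal: shortest-path walk stuck");
    path.push_back(best);
    u = best;
  }
  return IntegerVector(path.begin(), path.end());
}

// Farthest-point subsampling on geodesic distance. Starts from `start`,
// repeatedly adds the vertex farthest from the current sample set while that
// distance >= spacing. Returns sample ids, geodesic Voronoi owner (index into
// the sample list) for every vertex, and the distance-to-nearest-sample field.
// [[Rcpp::export]]
List fps_cpp(int n, IntegerVector ptr, IntegerVector idx, NumericVector w,
             int start, double spacing) {
  std::vector<double> mind(n, std::numeric_limits<double>::infinity());
  std::vector<int> owner(n, -1);
  std::vector<int> samples;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;

  int next = start;
  while (true) {
    int sid = (int)samples.size();
    samples.push_back(next);
    // single-source Dijkstra from `next`, relaxing against the global field
    mind[next] = 0.0; owner[next] = sid;
    while (!pq.empty()) pq.pop();
    pq.push(QE(0.0, next));
    while (!pq.empty()) {
      QE top = pq.top(); pq.pop();
      int u = top.second;
      if (top.first > mind[u] || owner[u] != sid) continue;
      for (int p = ptr[u]; p < ptr[u + 1]; ++p) {
        int v = idx[p];
        double nd = top.first + w[p];
        if (nd < mind[v]) { mind[v] = nd; owner[v] = sid; pq.push(QE(nd, v)); }
      }
    }
    // farthest remaining vertex (smallest id on ties, for determinism)
    double far = -1.0; int fari = -1;
    for (int i = 0; i < n; ++i)
      if (mind[i] > far + 1e-12) { far = mind[i]; fari = i; }
    if (fari < 0 || far < spacing) break;
    next = fari;
  }
  return List::create(_["samples"] = IntegerVector(samples.begin(), samples.end()),
                      _["owner"] = IntegerVector(owner.begin(), owner.end()),
                      _["mind"] = NumericVector(mind.begin(), mind.end()));
}

// Hungarian algorithm (potentials / shortest augmenting path), O(n^3).
// cost: n x n matrix; returns 0-based column assigned to each row.
// Infeasible entries may be +Inf; if no finite perfect matching exists the
// returned total is +Inf.
// [[Rcpp::export]]
List hungarian_cpp(NumericMatrix cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double c = cost(i0 - 1, j - 1);
        double cur = (std::isfinite(c) ? c : 1e18) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  IntegerVector assign(n);
  double total = 0.0;
  for (int j = 1; j <= n; ++j)
    if (p[j] > 0) assign[p[j] - 1] = j - 1;
  for (int i = 0; i < n; ++i) {
    double c = cost(i, assign[i]);
    total += c;
  }
  return List::create(_["assignment"] = assign, _["total"] = total);
}
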