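#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Pack a 3D grid cell into one 64-bit key (21 bits per axis; cloud extents
// of a few hundred metres at r >= 1 mm stay well within range).
static inline int64_t cell_key(int ix, int iy, int iz) {
  const int64_t B = 1 << 20;  // offset so indices are non-negative
  return (((int64_t)(ix + B)) << 42) | (((int64_t)(iy + B)) << 21) |
         ((int64_t)(iz + B));
}

// All point pairs within distance r, found by binning points into cells of
// side r and scanning the 27 surrounding cells. Optionally keep, per point,
// only the cap nearest candidates; an edge survives if either endpoint keeps
// it (union symmetrization).
// [[Rcpp::export]]
List cpp_radius_edges(NumericMatrix coords, double r, double cap) {
  const int n = coords.nrow();
  std::unordered_map<int64_t, std::vector<int>> grid;
  grid.reserve(n * 2);

  std::vector<int> cx(n), cy(n), cz(n);
  for (int p = 0; p < n; ++p) {
    cx[p] = (int)std::floor(coords(p, 0) / r);
    cy[p] = (int)std::floor(coords(p, 1) / r);
    cz[p] = (int)std::floor(coords(p, 2) / r);
    grid[cell_key(cx[p], cy[p], cz[p])].push_back(p);
  }

  std::vector<int> ei, ej;
  std::vector<double> ew;
  const double r2 = r * r;
  for (int p = 0; p < n; ++p) {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = grid.find(cell_key(cx[p] + dx, cy[p] + dy, cz[p] + dz));
          if (it == grid.end()) continue;
          for (int q : it->second) {
            if (q <= p) continue;  // each unordered pair once
            double a = coords(p, 0) - coords(q, 0);
            double b = coords(p, 1) - coords(q, 1);
            double c = coords(p, 2) - coords(q, 2);
            double d2 = a * a + b * b + c * c;
            if (d2 <= r2) {
              ei.push_back(p);
              ej.push_back(q);
              ew.push_back(std::sqrt(d2));
            }
          }
        }
  }

  int m = (int)ei.size();
  std::vector<char> keep(m, 1);
  if (R_finite(cap)) {
    int k = (int)cap;
    // rank incident edges per point by length; an edge is kept if it is
    // among the k nearest of either endpoint
    std::vector<std::vector<std::pair<double, int>>> inc(n);
    for (int e = 0; e < m; ++e) {
      inc[ei[e]].push_back({ew[e], e});
      inc[ej[e]].push_back({ew[e], e});
    }
    std::fill(keep.begin(), keep.end(), 0);
    for (int p = 0; p < n; ++p) {
      auto &v = inc[p];
      if ((int)v.size() > k)
        std::partial_sort(v.begin(), v.begin() + k, v.end());
      int lim = std::min((int)v.size(), k);
      for (int t = 0; t < lim; ++t) keep[v[t].second] = 1;
    }
  }

  int mk = 0;
  for (int e = 0; e < m; ++e) mk += keep[e];
  IntegerVector oi(mk), oj(mk);
  NumericVector ow(mk);
  for (int e = 0, t = 0; e < m; ++e) {
    if (!keep[e]) continue;
    oi[t] = ei[e] + 1;  // 1-based for R
    oj[t] = ej[e] + 1;
    ow[t] = ew[e];
    ++t;
  }
  return List::create(_["i"] = oi, _["j"] = oj, _["length"] = ow);
}

// Single-source shortest paths over an undirected weighted edge list.
// Ties between equal-length paths resolve to the smaller predecessor index,
// so the shortest-path tree is reproducible.
// [[Rcpp::export]]
List cpp_dijkstra(int n, IntegerVector ei, IntegerVector ej, NumericVector w,
                  int source) {
  std::vector<std::vector<std::pair<int, double>>> adj(n);
  const int m = ei.size();
  for (int e = 0; e < m; ++e) {
    int a = ei[e] - 1, b = ej[e] - 1;
    adj[a].push_back({b, w[e]});
    adj[b].push_back({a, w[e]});
  }

  std::vector<double> dist(n, R_PosInf);
  std::vector<int> pred(n, NA_INTEGER);
  std::vector<char> done(n, 0);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  int s = source - 1;
  dist[s] = 0.0;
  pq.push({0.0, s});
  while (!pq.empty()) {
    QE top = pq.top();
    pq.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    for (auto &ed : adj[u]) {
      int v = ed.first;
      double nd = dist[u] + ed.second;
      if (nd < dist[v]) {
        dist[v] = nd;
        pred[v] = u + 1;
        pq.push({nd, v});
      } else if (nd == dist[v] && pred[v] != NA_INTEGER && u + 1 < pred[v]) {
        pred[v] = u + 1;
      }
    }
  }

  NumericVector dout(n);
  IntegerVector pout(n);
  for (int p = 0; p < n; ++p) {
    dout[p] = dist[p];
    pout[p] = pred[p];
  }
  return List::create(_["dist"] = dout, _["pred"] = pout);
}
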