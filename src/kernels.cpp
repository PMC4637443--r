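#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Map 0-based integer voxel coordinates to a dense linear index lookup.
// coords: n x 3 integer matrix, assumed non-negative.
static std::vector<long long> make_lookup(const IntegerMatrix& coords,
                                          int& nx, int& ny, int& nz) {
  int n = coords.nrow();
  nx = ny = nz = 0;
  for (int i = 0; i < n; ++i) {
    if (coords(i, 0) >= nx) nx = coords(i, 0) + 1;
    if (coords(i, 1) >= ny) ny = coords(i, 1) + 1;
    if (coords(i, 2) >= nz) nz = coords(i, 2) + 1;
  }
  std::vector<long long> lut((long long)nx * ny * nz, -1);
  for (int i = 0; i < n; ++i) {
    long long key = coords(i, 0) + (long long)nx * (coords(i, 1) + (long long)ny * coords(i, 2));
    lut[key] = i;
  }
  return lut;
}

// First-arrival activation times over the 26-neighbour voxel graph.
// Edge travel time = euclidean length * (1/cv_a + 1/cv_b) / 2  (harmonic-mean
// velocity), cv in mm/ms, voxel_size in mm.  Multi-source Dijkstra seeded by
// (stim_idx, stim_delay).  Result in ms, rounded to `clock` ms resolution.
// [[Rcpp::export]]
NumericVector cpp_activation(IntegerMatrix coords, NumericVector cv,
                             double voxel_size, IntegerVector stim_idx,
                             NumericVector stim_delay, double clock) {
  int n = coords.nrow();
  if (stim_idx.size() == 0) stop("at least one stimulus site is required");
  int nx, ny, nz;
  std::vector<long long> lut = make_lookup(coords, nx, ny, nz);

  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> dist(n, inf);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (int s = 0; s < stim_idx.size(); ++s) {
    int i = stim_idx[s];
    if (i < 0 || i >= n) stop("stimulus index out of range");
    double d0 = stim_delay[s];
    if (d0 < dist[i]) { dist[i] = d0; pq.push(Node(d0, i)); }
  }

  // precompute the 26 offsets and their euclidean lengths
  int ox[26], oy[26], oz[26]; double olen[26]; int m = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        ox[m] = dx; oy[m] = dy; oz[m] = dz;
        olen[m] = voxel_size * std::sqrt((double)(dx * dx + dy * dy + dz * dz));
        ++m;
      }

  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    int u = top.second;
    if (top.first > dist[u]) continue;
    double inv_u = 1.0 / cv[u];
    for (int k = 0; k < 26; ++k) {
      int x = coords(u, 0) + ox[k], y = coords(u, 1) + oy[k], z = coords(u, 2) + oz[k];
      if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) continue;
      long long key = x + (long long)nx * (y + (long long)ny * z);
      long long v = lut[key];
      if (v < 0) continue;
      double alt = dist[u] + olen[k] * 0.5 * (inv_u + 1.0 / cv[v]);
      if (alt < dist[v]) { dist[v] = alt; pq.push(Node(alt, (int)v)); }
    }
  }

  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = std::isfinite(dist[i]) ? std::round(dist[i] / clock) * clock : R_PosInf;
  return out;
}

// For each row of `from`, euclidean distance to the nearest row of `to`
// (both in mm).  Brute force; sizes here are tens of thousands at most.
// [[Rcpp::export]]
NumericVector cpp_nearest_dist(NumericMatrix from, NumericMatrix to) {
  int n = from.nrow(), m = to.nrow();
  if (m == 0) stop("empty target point set");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    double xi = from(i, 0), yi = from(i, 1), zi = from(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = xi - to(j, 0), dy = yi - to(j, 1), dz = zi - to(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// 26-connectivity component labels (1-based) for a voxel set.
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerMatrix coords) {
  int n = coords.nrow();
  int nx, ny, nz;
  std::vector<long long> lut = make_lookup(coords, nx, ny, nz);
  IntegerVector label(n, 0);
  int cur = 0;
  std::vector<int> stack;
  for (int seed = 0; seed < n; ++seed) {
    if (label[seed]) continue;
    ++cur;
    stack.push_back(seed);
    label[seed] = cur;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x = coords(u, 0) + dx, y = coords(u, 1) + dy, z = coords(u, 2) + dz;
            if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) continue;
            long long v = lut[x + (long long)nx * (y + (long long)ny * z)];
            if (v >= 0 && !label[v]) { label[v] = cur; stack.push_back((int)v); }
          }
    }
  }
  return label;
}
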