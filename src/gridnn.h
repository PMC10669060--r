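#ifndef DENTREG_GRIDNN_H
#define DENTREG_GRIDNN_H

#include <RcppArmadillo.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

// Uniform-grid spatial index over 3D points (rows of an n x 3 matrix).
// Supports nearest-neighbour, bounded nearest and radius queries.
class Grid3 {
public:
  const arma::mat& pts;   // n x 3, not copied
  double cell;
  double minc[3];
  int dims[3];
  std::unordered_map<int64_t, std::vector<int>> cells;

  Grid3(const arma::mat& p, double cell_size) : pts(p), cell(cell_size) {
    if (cell <= 0) Rcpp::stop("grid cell size must be positive");
    for (int a = 0; a < 3; ++a) minc[a] = p.col(a).min();
    for (int a = 0; a < 3; ++a) {
      double span = p.col(a).max() - minc[a];
      dims[a] = std::max(1, (int)std::floor(span / cell) + 1);
    }
    cells.reserve(p.n_rows);
    for (arma::uword i = 0; i < p.n_rows; ++i) {
      cells[key_of(p(i,0), p(i,1), p(i,2))].push_back((int)i);
    }
  }

  inline int idx1(double x, int a) const {
    int v = (int)std::floor((x - minc[a]) / cell);
    if (v < 0) v = 0;
    if (v >= dims[a]) v = dims[a] - 1;
    return v;
  }
  inline int64_t key(int i, int j, int k) const {
    return ((int64_t)i << 42) | ((int64_t)j << 21) | (int64_t)k;
  }
  inline int64_t key_of(double x, double y, double z) const {
    return key(idx1(x,0), idx1(y,1), idx1(z,2));
  }

  // Nearest neighbour of q; returns index or -1 (if maxd>0 and nothing within maxd).
  // d2out receives squared distance.
  int nearest(const double* q, double maxd, double* d2out) const {
    // clamped center cell: for any grid point p, ||p-q|| >= ||p-qc|| where qc
    // is the projection of q onto the grid box, so (r-1)*cell from the clamped
    // center remains a valid ring lower bound.
    int ci = idx1(q[0], 0), cj = idx1(q[1], 1), ck = idx1(q[2], 2);
    double best = std::numeric_limits<double>::infinity();
    if (maxd > 0) best = maxd * maxd;
    int besti = -1;
    int max_ring = std::max(dims[0], std::max(dims[1], dims[2])) + 1;
    for (int r = 0; r <= max_ring; ++r) {
      if (r > 0) {
        double lb = (double)(r - 1) * cell;
        if (lb * lb > best) break;
      }
      for (int i = ci - r; i <= ci + r; ++i) {
        if (i < 0 || i >= dims[0]) continue;
        for (int j = cj - r; j <= cj + r; ++j) {
          if (j < 0 || j >= dims[1]) continue;
          for (int k = ck - r; k <= ck + r; ++k) {
            if (k < 0 || k >= dims[2]) continue;
            int cheb = std::max(std::abs(i-ci), std::max(std::abs(j-cj), std::abs(k-ck)));
            if (cheb != r) continue;
            auto it = cells.find(key(i,j,k));
            if (it == cells.end()) continue;
            for (int p : it->second) {
              double dx = pts(p,0)-q[0], dy = pts(p,1)-q[1], dz = pts(p,2)-q[2];
              double d2 = dx*dx + dy*dy + dz*dz;
              if (d2 < best) { best = d2; besti = p; }
            }
          }
        }
      }
    }
    *d2out = best;
    return besti;
  }

  // All point indices within radius rad of q.
  void radius(const double* q, double rad, std::vector<int>& out) const {
    out.clear();
    double r2 = rad * rad;
    int i0 = cell_index_unclamped(q[0]-rad, 0), i1 = cell_index_unclamped(q[0]+rad, 0);
    int j0 = cell_index_unclamped(q[1]-rad, 1), j1 = cell_index_unclamped(q[1]+rad, 1);
    int k0 = cell_index_unclamped(q[2]-rad, 2), k1 = cell_index_unclamped(q[2]+rad, 2);
    i0 = std::max(i0, 0); j0 = std::max(j0, 0); k0 = std::max(k0, 0);
    i1 = std::min(i1, dims[0]-1); j1 = std::min(j1, dims[1]-1); k1 = std::min(k1, dims[2]-1);
    for (int i = i0; i <= i1; ++i)
      for (int j = j0; j <= j1; ++j)
        for (int k = k0; k <= k1; ++k) {
          auto it = cells.find(key(i,j,k));
          if (it == cells.end()) continue;
          for (int p : it->second) {
            double dx = pts(p,0)-q[0], dy = pts(p,1)-q[1], dz = pts(p,2)-q[2];
            if (dx*dx + dy*dy + dz*dz <= r2) out.push_back(p);
          }
        }
  }

  // k nearest neighbours (indices), excluding point index `exclude` (-1 for none).
  void knn(const double* q, int k, int exclude, std::vector<int>& out) const {
    out.clear();
    double rad = cell;
    int n = (int)pts.n_rows;
    if (k >= n - (exclude >= 0 ? 1 : 0)) {
      for (int i = 0; i < n; ++i) if (i != exclude) out.push_back(i);
      std::sort(out.begin(), out.end(), [&](int a, int b) {
        return d2(a, q) < d2(b, q); });
      return;
    }
    std::vector<int> cand;
    double span = std::max({(dims[0]+1)*cell, (dims[1]+1)*cell, (dims[2]+1)*cell});
    while (true) {
      radius(q, rad, cand);
      int have = (int)cand.size() - (exclude >= 0 &&
        std::find(cand.begin(), cand.end(), exclude) != cand.end() ? 1 : 0);
      if (have >= k) {
        std::sort(cand.begin(), cand.end(), [&](int a, int b) {
          return d2(a, q) < d2(b, q); });
        // candidates beyond rad may still be closer than the kth within bounding
        // box corners; enlarge once by the kth distance to be safe.
        int cnt = 0; double dk = 0;
        for (int idx : cand) { if (idx == exclude) continue; if (++cnt == k) { dk = std::sqrt(d2(idx, q)); break; } }
        if (dk > rad) { rad = dk * 1.0000001; continue; }
        out.reserve(k); cnt = 0;
        for (int idx : cand) { if (idx == exclude) continue; out.push_back(idx); if (++cnt == k) break; }
        return;
      }
      rad *= 2.0;
      if (rad > 4.0 * span) { // fall back: take all
        out.clear();
        for (int i = 0; i < n; ++i) if (i != exclude) out.push_back(i);
        std::sort(out.begin(), out.end(), [&](int a, int b) {
          return d2(a, q) < d2(b, q); });
        if ((int)out.size() > k) out.resize(k);
        return;
      }
    }
  }

private:
  inline int cell_index_unclamped(double x, int a) const {
    return (int)std::floor((x - minc[a]) / cell);
  }
  inline double d2(int i, const double* q) const {
    double dx = pts(i,0)-q[0], dy = pts(i,1)-q[1], dz = pts(i,2)-q[2];
    return dx*dx + dy*dy + dz*dz;
  }
};

// Heuristic cell size: the largest axis span divided by n^(1/3), which
// bounds the grid at ~n cells even for planar or collinear clouds.
inline double grid_cell_heuristic(const arma::mat& p) {
  double m = 0.0;
  for (int a = 0; a < 3; ++a)
    m = std::max(m, p.col(a).max() - p.col(a).min());
  double c = m / std::max(1.0, std::cbrt((double)p.n_rows));
  if (!(c > 0) || !std::isfinite(c)) c = 1.0;
  return c;
}

#endif
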