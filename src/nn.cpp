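// [[Rcpp::depends(RcppArmadillo)]]
#include "gridnn.h"
#include <queue>

using namespace Rcpp;

// Nearest-neighbour distances (and 1-based indices) from each query row to
// the target cloud.
// [[Rcpp::export]]
List cpp_nn(const arma::mat& query, const arma::mat& target) {
  if (target.n_rows == 0 || query.n_rows == 0) stop("empty point set");
  Grid3 g(target, grid_cell_heuristic(target));
  arma::uword n = query.n_rows;
  NumericVector d(n);
  IntegerVector idx(n);
  for (arma::uword i = 0; i < n; ++i) {
    double q[3] = {query(i,0), query(i,1), query(i,2)};
    double d2;
    int j = g.nearest(q, -1.0, &d2);
    d[i] = std::sqrt(d2);
    idx[i] = j + 1;
  }
  return List::create(_["dist"] = d, _["index"] = idx);
}

// Bounded nearest neighbour: index 0 and dist Inf where nothing lies within
// max_dist.
// [[Rcpp::export]]
List cpp_nn_within(const arma::mat& query, const arma::mat& target,
                   double max_dist) {
  if (target.n_rows == 0 || query.n_rows == 0) stop("empty point set");
  double cell = std::min(grid_cell_heuristic(target), max_dist);
  Grid3 g(target, cell);
  arma::uword n = query.n_rows;
  NumericVector d(n);
  IntegerVector idx(n);
  for (arma::uword i = 0; i < n; ++i) {
    double q[3] = {query(i,0), query(i,1), query(i,2)};
    double d2;
    int j = g.nearest(q, max_dist, &d2);
    d[i] = (j >= 0) ? std::sqrt(d2) : R_PosInf;
    idx[i] = j + 1;
  }
  return List::create(_["dist"] = d, _["index"] = idx);
}

// Voxel-grid downsampling: one centroid per occupied bucket. Colors and
// normals (possibly 0 x 3) are averaged; normals are renormalised in R.
// Buckets are indexed by floor((p - min) / voxel).
// [[Rcpp::export]]
List cpp_voxel_downsample(const arma::mat& pts, const arma::mat& colors,
                          const arma::mat& normals, double voxel) {
  if (voxel <= 0) stop("voxel size must be positive");
  arma::uword n = pts.n_rows;
  bool has_col = colors.n_rows == n, has_nrm = normals.n_rows == n;
  double minc[3];
  for (int a = 0; a < 3; ++a) minc[a] = pts.col(a).min();
  std::unordered_map<int64_t, int> bucket_of;
  bucket_of.reserve(n);
  std::vector<std::array<double,10>> acc; // x y z r g b nx ny nz count
  std::vector<int64_t> bucket_key;
  for (arma::uword i = 0; i < n; ++i) {
    int64_t ix = (int64_t)std::floor((pts(i,0) - minc[0]) / voxel);
    int64_t iy = (int64_t)std::floor((pts(i,1) - minc[1]) / voxel);
    int64_t iz = (int64_t)std::floor((pts(i,2) - minc[2]) / voxel);
    int64_t k = (ix << 42) | (iy << 21) | iz;
    auto it = bucket_of.find(k);
    int b;
    if (it == bucket_of.end()) {
      b = (int)acc.size();
      bucket_of[k] = b;
      acc.push_back({0,0,0,0,0,0,0,0,0,0});
      bucket_key.push_back(k);
    } else b = it->second;
    auto& a = acc[b];
    a[0] += pts(i,0); a[1] += pts(i,1); a[2] += pts(i,2);
    if (has_col) { a[3] += colors(i,0); a[4] += colors(i,1); a[5] += colors(i,2); }
    if (has_nrm) { a[6] += normals(i,0); a[7] += normals(i,1); a[8] += normals(i,2); }
    a[9] += 1.0;
  }
  int m = (int)acc.size();
  arma::mat out(m, 3), ocol(has_col ? m : 0, 3), onrm(has_nrm ? m : 0, 3);
  IntegerVector counts(m);
  for (int b = 0; b < m; ++b) {
    double c = acc[b][9];
    out(b,0) = acc[b][0]/c; out(b,1) = acc[b][1]/c; out(b,2) = acc[b][2]/c;
    if (has_col) { ocol(b,0)=acc[b][3]/c; ocol(b,1)=acc[b][4]/c; ocol(b,2)=acc[b][5]/c; }
    if (has_nrm) { onrm(b,0)=acc[b][6]/c; onrm(b,1)=acc[b][7]/c; onrm(b,2)=acc[b][8]/c; }
    counts[b] = (int)c;
  }
  return List::create(_["points"] = out, _["colors"] = ocol,
                      _["normals"] = onrm, _["counts"] = counts);
}

// Per-point normals from the smallest eigenvector of the k-neighbourhood
// covariance. Orientation: mode 0 propagates consistency along the kNN
// graph by BFS from the point farthest from the centroid (seeded to face
// outward) — right for thin surface samples; mode 1 points each normal
// away from its neighbourhood centroid (local density gradient) — right
// for the shell of a filled voxel cloud, where the interior pulls the
// centroid inward. Column 4 of the result is the surface variation
// lambda0/(l0+l1+l2) (~0 on a smooth surface, ~1/3 inside an isotropic
// solid).
// [[Rcpp::export]]
arma::mat cpp_estimate_normals(const arma::mat& pts, int k, int orient_mode = 0) {
  arma::uword n = pts.n_rows;
  if ((arma::uword)k >= n) stop("k_neighbors must be smaller than the number of points");
  Grid3 g(pts, grid_cell_heuristic(pts));
  arma::mat nrm(n, 4, arma::fill::zeros);
  std::vector<std::vector<int>> nbrs(n);
  std::vector<int> nb;
  for (arma::uword i = 0; i < n; ++i) {
    double q[3] = {pts(i,0), pts(i,1), pts(i,2)};
    g.knn(q, k, (int)i, nb);
    nbrs[i] = nb;
    arma::mat P(nb.size() + 1, 3);
    for (size_t j = 0; j < nb.size(); ++j) P.row(j) = pts.row(nb[j]);
    P.row(nb.size()) = pts.row(i);
    arma::rowvec mu = arma::mean(P, 0);
    P.each_row() -= mu;
    arma::mat C = P.t() * P;
    arma::vec eval; arma::mat evec;
    if (!arma::eig_sym(eval, evec, C)) stop("eigendecomposition failed");
    arma::vec v = evec.col(0); // smallest eigenvalue
    double vn = arma::norm(v);
    nrm(i,0) = v[0]/vn; nrm(i,1) = v[1]/vn; nrm(i,2) = v[2]/vn;
    double tot = arma::accu(arma::abs(eval));
    nrm(i,3) = tot > 0 ? std::fabs(eval[0]) / tot : 0.0;
    if (orient_mode == 1) {
      arma::rowvec away = pts.row(i) - mu;
      if (away(0)*nrm(i,0) + away(1)*nrm(i,1) + away(2)*nrm(i,2) < 0) {
        nrm(i,0) = -nrm(i,0); nrm(i,1) = -nrm(i,1); nrm(i,2) = -nrm(i,2);
      }
    }
  }
  if (orient_mode == 1) return nrm;
  // Orientation propagation along a minimum spanning tree weighted by
  // 1 - |n_i . n_j| (Hoppe-style): orientation spreads through smooth
  // regions first. Edges that run along the normals rather than along the
  // surface (|n . d| large for the unit edge vector d) connect *facing*
  // sheets — e.g. the opposing walls of adjacent tooth crowns — where the
  // parent/child flip rule inverts orientation; those edges are cut, and
  // each remaining component is seeded at its point farthest from the
  // component centroid, oriented away from it.
  auto nvec = [&](int i) { return nrm.submat(i, 0, i, 2); };
  for (arma::uword i = 0; i < n; ++i) {
    std::vector<int> keep;
    for (int j : nbrs[i]) {
      arma::rowvec d = pts.row(j) - pts.row(i);
      double dn = arma::norm(d);
      if (dn < 1e-12) { keep.push_back(j); continue; }
      d /= dn;
      double along = std::fabs(arma::dot(nvec((int)i), d)) +
                     std::fabs(arma::dot(nvec(j), d));
      if (along <= 1.0) keep.push_back(j);
    }
    nbrs[i] = keep;
  }
  // symmetrize
  for (arma::uword i = 0; i < n; ++i)
    for (int j : nbrs[i])
      if (std::find(nbrs[j].begin(), nbrs[j].end(), (int)i) == nbrs[j].end())
        nbrs[j].push_back((int)i);
  // connected components of the pruned graph
  std::vector<int> comp(n, -1);
  int ncomp = 0;
  for (arma::uword i = 0; i < n; ++i) {
    if (comp[i] >= 0) continue;
    std::queue<int> bfs;
    bfs.push((int)i);
    comp[i] = ncomp;
    while (!bfs.empty()) {
      int u = bfs.front(); bfs.pop();
      for (int v : nbrs[u]) if (comp[v] < 0) { comp[v] = ncomp; bfs.push(v); }
    }
    ++ncomp;
  }
  arma::mat ccent(ncomp, 3, arma::fill::zeros);
  arma::vec csize(ncomp, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    ccent.row(comp[i]) += pts.row(i);
    csize[comp[i]] += 1.0;
  }
  ccent.each_col() /= csize;
  std::vector<char> visited(n, 0);
  typedef std::pair<double, std::pair<int,int>> QE; // weight, (from, to)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  for (arma::uword seed = 0; seed < n; ++seed) {
    if (visited[seed]) continue;
    visited[seed] = 1;
    for (int v : nbrs[seed])
      pq.push({1.0 - std::fabs(arma::dot(nvec((int)seed), nvec(v))),
               {(int)seed, v}});
    while (!pq.empty()) {
      QE e = pq.top(); pq.pop();
      int u = e.second.first, v = e.second.second;
      if (visited[v]) continue;
      if (arma::dot(nvec(u), nvec(v)) < 0) nvec(v) *= -1.0;
      visited[v] = 1;
      for (int w : nbrs[v])
        if (!visited[w])
          pq.push({1.0 - std::fabs(arma::dot(nvec(v), nvec(w))), {v, w}});
    }
  }
  // global sign per component: majority vote of outwardness from the
  // component centroid (robust where a single seed point could sit on a
  // concave spot and invert the whole component)
  arma::vec vote(ncomp, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    arma::rowvec outward = pts.row(i) - ccent.row(comp[i]);
    double no = arma::norm(outward);
    if (no > 1e-12) vote[comp[i]] += arma::dot(outward / no, nvec((int)i));
  }
  for (arma::uword i = 0; i < n; ++i)
    if (vote[comp[i]] < 0) nvec((int)i) *= -1.0;
  return nrm;
}

// Euclidean clustering: connected components of the "within radius" graph.
// Returns 1-based cluster id per point.
// [[Rcpp::export]]
IntegerVector cpp_euclidean_cluster(const arma::mat& pts, double radius) {
  arma::uword n = pts.n_rows;
  if (radius <= 0) stop("radius must be positive");
  Grid3 g(pts, radius);
  IntegerVector lab(n, 0);
  std::vector<int> nb;
  int next = 0;
  for (arma::uword i = 0; i < n; ++i) {
    if (lab[i] != 0) continue;
    ++next;
    std::queue<int> bfs;
    bfs.push((int)i);
    lab[i] = next;
    while (!bfs.empty()) {
      int u = bfs.front(); bfs.pop();
      double q[3] = {pts(u,0), pts(u,1), pts(u,2)};
      g.radius(q, radius, nb);
      for (int v : nb) {
        if (lab[v] == 0) { lab[v] = next; bfs.push(v); }
      }
    }
  }
  return lab;
}

// 8-connected component labelling of a binary matrix. Returns an integer
// matrix of labels (0 = background), labels numbered from 1 in scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int,int>> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i,j) || lab(i,j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({i,j});
      lab(i,j) = next;
      while (!stack.empty()) {
        auto [ci, cj] = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (mask(ni,nj) && lab(ni,nj) == 0) {
              lab(ni,nj) = next;
              stack.push_back({ni,nj});
            }
          }
      }
    }
  }
  return lab;
}
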