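// [[Rcpp::depends(RcppArmadillo)]]
#include "gridnn.h"
using namespace Rcpp;

// Darboux-frame pair features (alpha, phi, theta) binned 11 ways each.
static inline void pair_feature(const double* ps, const double* ns,
                                const double* pt, const double* nt,
                                double* f) {
  double d[3] = {pt[0]-ps[0], pt[1]-ps[1], pt[2]-ps[2]};
  double dist = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
  if (dist < 1e-12) { f[0] = f[1] = f[2] = 0; return; }
  d[0] /= dist; d[1] /= dist; d[2] /= dist;
  const double* u = ns;
  double v[3] = {u[1]*d[2]-u[2]*d[1], u[2]*d[0]-u[0]*d[2], u[0]*d[1]-u[1]*d[0]};
  double vn = std::sqrt(v[0]*v[0]+v[1]*v[1]+v[2]*v[2]);
  if (vn < 1e-12) { f[0] = f[1] = f[2] = 0; return; }
  v[0]/=vn; v[1]/=vn; v[2]/=vn;
  double w[3] = {u[1]*v[2]-u[2]*v[1], u[2]*v[0]-u[0]*v[2], u[0]*v[1]-u[1]*v[0]};
  f[0] = v[0]*nt[0] + v[1]*nt[1] + v[2]*nt[2];            // alpha in [-1,1]
  f[1] = u[0]*d[0] + u[1]*d[1] + u[2]*d[2];               // phi in [-1,1]
  f[2] = std::atan2(w[0]*nt[0]+w[1]*nt[1]+w[2]*nt[2],
                    u[0]*nt[0]+u[1]*nt[1]+u[2]*nt[2]);    // theta in [-pi,pi]
}

static inline int bin11(double x, double lo, double hi) {
  int b = (int)(11.0 * (x - lo) / (hi - lo));
  if (b < 0) b = 0;
  if (b > 10) b = 10;
  return b;
}

// Fast point feature histograms (33 bins) over a metric radius.
// Two passes: simplified histograms (SPFH), then distance-weighted
// combination over the same neighbourhoods. Each 11-bin block of the result
// is normalised to unit sum.
// [[Rcpp::export]]
arma::mat cpp_fpfh(const arma::mat& pts, const arma::mat& normals,
                   double radius) {
  arma::uword n = pts.n_rows;
  if (normals.n_rows != n) stop("points/normals size mismatch");
  Grid3 g(pts, radius / 2.0);
  arma::mat spfh(33, n, arma::fill::zeros);
  std::vector<int> nb;
  std::vector<std::vector<int>> nbrs(n);
  for (arma::uword i = 0; i < n; ++i) {
    double q[3] = {pts(i,0), pts(i,1), pts(i,2)};
    g.radius(q, radius, nb);
    double ps[3] = {pts(i,0), pts(i,1), pts(i,2)};
    double ns[3] = {normals(i,0), normals(i,1), normals(i,2)};
    int cnt = 0;
    std::vector<int>& keep = nbrs[i];
    for (int j : nb) {
      if ((arma::uword)j == i) continue;
      keep.push_back(j);
      double pt[3] = {pts(j,0), pts(j,1), pts(j,2)};
      double nt[3] = {normals(j,0), normals(j,1), normals(j,2)};
      double f[3];
      pair_feature(ps, ns, pt, nt, f);
      spfh(bin11(f[0], -1.0, 1.0), i) += 1.0;
      spfh(11 + bin11(f[1], -1.0, 1.0), i) += 1.0;
      spfh(22 + bin11(f[2], -M_PI, M_PI), i) += 1.0;
      ++cnt;
    }
    if (cnt > 0) spfh.col(i) /= (double)cnt;
  }
  arma::mat fpfh(33, n, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    fpfh.col(i) = spfh.col(i);
    const std::vector<int>& keep = nbrs[i];
    if (!keep.empty()) {
      arma::vec acc(33, arma::fill::zeros);
      int used = 0;
      for (int j : keep) {
        double dx = pts(j,0)-pts(i,0), dy = pts(j,1)-pts(i,1), dz = pts(j,2)-pts(i,2);
        double w = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (w < 1e-12) continue;
        acc += spfh.col(j) / w;
        ++used;
      }
      if (used > 0) fpfh.col(i) += acc / (double)used;
    }
    // normalise each 11-bin block
    for (int b = 0; b < 3; ++b) {
      double s = arma::accu(fpfh.col(i).subvec(11*b, 11*b+10));
      if (s > 0) fpfh.col(i).subvec(11*b, 11*b+10) /= s;
    }
  }
  return fpfh;
}
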