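// [[Rcpp::depends(RcppArmadillo)]]
#include "gridnn.h"
using namespace Rcpp;

// Closed-form least-squares rigid transform (Kabsch/Umeyama, no scaling)
// mapping src rows onto dst rows. Returns 4x4 homogeneous matrix.
static arma::mat kabsch(const arma::mat& src, const arma::mat& dst) {
  arma::rowvec cs = arma::mean(src, 0), cd = arma::mean(dst, 0);
  arma::mat S = src.each_row() - cs, D = dst.each_row() - cd;
  arma::mat H = S.t() * D;
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) return arma::mat(4,4,arma::fill::eye);
  arma::mat R = V * U.t();
  if (arma::det(R) < 0) {
    V.col(2) *= -1.0;
    R = V * U.t();
  }
  arma::vec t = cd.t() - R * cs.t();
  arma::mat T(4, 4, arma::fill::eye);
  T.submat(0,0,2,2) = R;
  T.submat(0,3,2,3) = t;
  return T;
}

// [[Rcpp::export]]
arma::mat cpp_kabsch(const arma::mat& src, const arma::mat& dst) {
  return kabsch(src, dst);
}

static void eval_transform(const arma::mat& T, const arma::mat& src,
                           const Grid3& g, double inlier_dist,
                           const std::vector<int>& subset,
                           double* fitness, double* rmse) {
  arma::mat R = T.submat(0,0,2,2);
  arma::vec t = T.submat(0,3,2,3);
  int n = (int)subset.size(), cnt = 0;
  double ss = 0;
  for (int idx : subset) {
    arma::vec p = R * src.row(idx).t() + t;
    double q[3] = {p[0], p[1], p[2]};
    double d2;
    int j = g.nearest(q, inlier_dist, &d2);
    if (j >= 0) { ++cnt; ss += d2; }
  }
  *fitness = n > 0 ? (double)cnt / n : 0.0;
  *rmse = cnt > 0 ? std::sqrt(ss / cnt) : 0.0;
}

// pose distance helpers for hypothesis diversity
static double rot_angle_between(const arma::mat& A, const arma::mat& B) {
  arma::mat R = A.submat(0,0,2,2).t() * B.submat(0,0,2,2);
  double c = (arma::trace(R) - 1.0) / 2.0;
  c = std::min(1.0, std::max(-1.0, c));
  return std::acos(c) * 180.0 / M_PI;
}
static double trans_dist_between(const arma::mat& A, const arma::mat& B) {
  return arma::norm(A.submat(0,3,2,3) - B.submat(0,3,2,3));
}

// RANSAC over precomputed feature correspondences (corr: 1-based target
// index per source point). samples: max_iter x 3 matrix of 1-based source
// indices drawn in R (keeps the hypothesis stream under R's RNG). Hypotheses
// are pruned by pairwise edge-length similarity, scored by inlier fitness on
// score_idx (1-based subset of source points), and the best is re-scored on
// the full source cloud. Early stop at the standard RANSAC confidence bound,
// but never before min_iter samples: near-symmetric shapes (a dental arch
// is almost mirror-symmetric) produce a competing pose basin, so the best
// hypothesis from a *pose-distinct* second basin is also returned for the
// fine stage to disambiguate.
// [[Rcpp::export]]
List cpp_ransac(const arma::mat& src, const arma::mat& tgt,
                const IntegerVector& corr, const IntegerMatrix& samples,
                double edge_sim, double inlier_dist,
                const IntegerVector& score_idx, double confidence,
                double min_fitness, int min_iter) {
  Grid3 g(tgt, inlier_dist);
  std::vector<int> subset(score_idx.size());
  for (int i = 0; i < score_idx.size(); ++i) subset[i] = score_idx[i] - 1;
  std::vector<int> full(src.n_rows);
  for (arma::uword i = 0; i < src.n_rows; ++i) full[i] = (int)i;

  arma::mat bestT(4,4,arma::fill::eye), altT(4,4,arma::fill::eye);
  double best_fit = -1.0, best_rmse = R_PosInf;
  double alt_fit = -1.0, alt_rmse = R_PosInf;
  bool have = false, have_alt = false;
  const double DIV_ANG = 20.0, DIV_TRANS = 5.0; // "different basin" margins
  int used_iter = 0;
  int max_iter = samples.nrow();
  double needed = (double)max_iter;
  arma::mat s3(3,3), d3(3,3);
  for (int it = 0; it < max_iter; ++it) {
    used_iter = it + 1;
    int i1 = samples(it,0)-1, i2 = samples(it,1)-1, i3 = samples(it,2)-1;
    int t1 = corr[i1]-1, t2 = corr[i2]-1, t3 = corr[i3]-1;
    if (t1 == t2 || t1 == t3 || t2 == t3) continue;
    // edge-length similarity pruning
    bool ok = true;
    int si[3] = {i1,i2,i3}, ti[3] = {t1,t2,t3};
    for (int a = 0; a < 3 && ok; ++a) {
      int b = (a+1) % 3;
      double ls = arma::norm(src.row(si[a]) - src.row(si[b]));
      double lt = arma::norm(tgt.row(ti[a]) - tgt.row(ti[b]));
      double mx = std::max(ls, lt), mn = std::min(ls, lt);
      if (mx < 1e-9 || mn / mx < edge_sim) ok = false;
    }
    if (!ok) continue;
    for (int a = 0; a < 3; ++a) {
      s3.row(a) = src.row(si[a]);
      d3.row(a) = tgt.row(ti[a]);
    }
    arma::mat T = kabsch(s3, d3);
    double fit, rmse;
    eval_transform(T, src, g, inlier_dist, subset, &fit, &rmse);
    bool distinct = !have ||
      rot_angle_between(T, bestT) > DIV_ANG ||
      trans_dist_between(T, bestT) > DIV_TRANS;
    if (fit > best_fit || (fit == best_fit && rmse < best_rmse)) {
      // the displaced best may itself seed the alternative basin
      if (have && distinct &&
          (best_fit > alt_fit || (best_fit == alt_fit && best_rmse < alt_rmse))) {
        altT = bestT; alt_fit = best_fit; alt_rmse = best_rmse; have_alt = true;
      }
      best_fit = fit; best_rmse = rmse; bestT = T; have = true;
      if (have_alt && rot_angle_between(altT, bestT) <= DIV_ANG &&
          trans_dist_between(altT, bestT) <= DIV_TRANS) {
        have_alt = false; alt_fit = -1.0; alt_rmse = R_PosInf;
      }
      if (fit > 0) {
        double p3 = fit * fit * fit;
        needed = std::log(std::max(1e-12, 1.0 - confidence)) /
                 std::log(std::max(1e-12, 1.0 - p3));
      }
    } else if (distinct &&
               (fit > alt_fit || (fit == alt_fit && rmse < alt_rmse))) {
      altT = T; alt_fit = fit; alt_rmse = rmse; have_alt = true;
    }
    if (have && best_fit >= min_fitness && (double)(it + 1) >= needed &&
        (it + 1) >= min_iter) break;
  }
  double fit_full = 0.0, rmse_full = 0.0;
  if (have) eval_transform(bestT, src, g, inlier_dist, full, &fit_full, &rmse_full);
  double afit_full = 0.0, armse_full = 0.0;
  if (have_alt) eval_transform(altT, src, g, inlier_dist, full, &afit_full, &armse_full);
  return List::create(_["transform"] = bestT, _["fitness"] = fit_full,
                      _["inlier_rmse"] = rmse_full,
                      _["iterations"] = used_iter, _["found"] = have,
                      _["alt_transform"] = altT, _["alt_fitness"] = afit_full,
                      _["alt_inlier_rmse"] = armse_full,
                      _["has_alternative"] = have_alt);
}

// Point-to-plane ICP. Correspondences: nearest target point within max_corr.
// Inner solve: small-angle linearisation (omega, t) of
// sum_i ((R p_i + t - q_i) . n_i)^2, closed form via 6x6 normal equations,
// with step halving so the objective at fixed correspondences never
// increases. Convergence: relative change of fitness and inlier RMSE < tol.
// [[Rcpp::export]]
List cpp_icp_point_to_plane(const arma::mat& src, const arma::mat& tgt,
                            const arma::mat& tgt_nrm, const arma::mat& T0,
                            double max_corr, int max_iter, double tol) {
  Grid3 g(tgt, max_corr);
  arma::mat T = T0;
  double prev_fit = -1.0, prev_rmse = -1.0;
  double fit = 0.0, rmse = 0.0;
  bool converged = false;
  int iters = 0;
  NumericVector obj_before, obj_after;
  arma::uword n = src.n_rows;
  for (int it = 0; it < max_iter; ++it) {
    iters = it + 1;
    arma::mat R = T.submat(0,0,2,2);
    arma::vec t = T.submat(0,3,2,3);
    // correspondences at current pose
    std::vector<int> is, js;
    is.reserve(n); js.reserve(n);
    double ss = 0;
    for (arma::uword i = 0; i < n; ++i) {
      arma::vec p = R * src.row(i).t() + t;
      double q[3] = {p[0], p[1], p[2]};
      double d2;
      int j = g.nearest(q, max_corr, &d2);
      if (j >= 0) { is.push_back((int)i); js.push_back(j); ss += d2; }
    }
    if (is.empty()) {
      return List::create(_["transform"] = T, _["fitness"] = 0.0,
                          _["inlier_rmse"] = 0.0, _["iterations"] = iters,
                          _["converged"] = false, _["no_correspondences"] = true,
                          _["obj_before"] = obj_before, _["obj_after"] = obj_after);
    }
    fit = (double)is.size() / (double)n;
    rmse = std::sqrt(ss / is.size());
    // convergence on relative change of both fitness and inlier RMSE
    if (it > 0) {
      double df = std::fabs(fit - prev_fit) / std::max(prev_fit, 1e-12);
      double dr = std::fabs(rmse - prev_rmse) / std::max(prev_rmse, 1e-12);
      if (df < tol && dr < tol) { converged = true; break; }
    }
    prev_fit = fit; prev_rmse = rmse;
    // build normal equations for the point-to-plane objective
    arma::mat A(6,6,arma::fill::zeros);
    arma::vec b(6,arma::fill::zeros);
    double obj0 = 0;
    for (size_t m = 0; m < is.size(); ++m) {
      arma::vec p = R * src.row(is[m]).t() + t;
      arma::vec q = tgt.row(js[m]).t();
      arma::vec nv = tgt_nrm.row(js[m]).t();
      double r = arma::dot(p - q, nv);
      obj0 += r * r;
      arma::vec J(6);
      arma::vec cx = arma::cross(p, nv);
      J.subvec(0,2) = cx;
      J.subvec(3,5) = nv;
      A += J * J.t();
      b -= J * r;
    }
    obj_before.push_back(obj0);
    arma::vec x;
    // scaled Tikhonov damping keeps under-constrained geometries (e.g. a
    // plane, which leaves in-plane motion free) well posed
    double lam = 1e-9 * (arma::trace(A) / 6.0 + 1.0);
    bool solved = arma::solve(x, A + lam * arma::eye(6,6), b);
    if (!solved) { converged = false; break; }
    // step halving: guarantee non-increase of the fixed-correspondence objective
    double scale = 1.0;
    arma::mat Tnew = T;
    double obj1 = obj0;
    for (int h = 0; h < 20; ++h) {
      arma::vec w = x.subvec(0,2) * scale;
      arma::vec dt = x.subvec(3,5) * scale;
      double ang = arma::norm(w);
      arma::mat dR(3,3,arma::fill::eye);
      if (ang > 1e-15) {
        arma::vec ax = w / ang;
        arma::mat K = {{0,-ax[2],ax[1]},{ax[2],0,-ax[0]},{-ax[1],ax[0],0}};
        dR = arma::eye(3,3) + std::sin(ang)*K + (1-std::cos(ang))*(K*K);
      }
      arma::mat Tc(4,4,arma::fill::eye);
      Tc.submat(0,0,2,2) = dR;
      Tc.submat(0,3,2,3) = dt;
      arma::mat Ttry = Tc * T;
      arma::mat Rn = Ttry.submat(0,0,2,2);
      arma::vec tn = Ttry.submat(0,3,2,3);
      double o = 0;
      for (size_t m = 0; m < is.size(); ++m) {
        arma::vec p = Rn * src.row(is[m]).t() + tn;
        double r = arma::dot(p - tgt.row(js[m]).t(), tgt_nrm.row(js[m]).t());
        o += r * r;
      }
      if (o <= obj0 + 1e-12) { Tnew = Ttry; obj1 = o; break; }
      scale *= 0.5;
    }
    obj_after.push_back(obj1);
    T = Tnew;
  }
  // final metrics at the converged pose
  arma::mat R = T.submat(0,0,2,2);
  arma::vec t = T.submat(0,3,2,3);
  double ss = 0;
  int cnt = 0;
  for (arma::uword i = 0; i < n; ++i) {
    arma::vec p = R * src.row(i).t() + t;
    double q[3] = {p[0], p[1], p[2]};
    double d2;
    int j = g.nearest(q, max_corr, &d2);
    if (j >= 0) { ++cnt; ss += d2; }
  }
  fit = (double)cnt / (double)n;
  rmse = cnt > 0 ? std::sqrt(ss / cnt) : 0.0;
  return List::create(_["transform"] = T, _["fitness"] = fit,
                      _["inlier_rmse"] = rmse, _["iterations"] = iters,
                      _["converged"] = converged,
                      _["no_correspondences"] = false,
                      _["obj_before"] = obj_before, _["obj_after"] = obj_after);
}
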