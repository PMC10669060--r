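// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Trilinear interpolation of a volume (R column-major, dims nx,ny,nz) at a
// continuous 0-based voxel coordinate; out-of-bounds contributes `background`.
static inline double sample_trilinear(const double* vol, int nx, int ny, int nz,
                                      double x, double y, double z,
                                      double background) {
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz) {
    double wz = dz ? fz : 1.0 - fz;
    if (wz == 0.0) continue;
    for (int dy = 0; dy <= 1; ++dy) {
      double wy = dy ? fy : 1.0 - fy;
      if (wy == 0.0) continue;
      for (int dx = 0; dx <= 1; ++dx) {
        double wx = dx ? fx : 1.0 - fx;
        if (wx == 0.0) continue;
        int xi = x0 + dx, yi = y0 + dy, zi = z0 + dz;
        double v;
        if (xi < 0 || xi >= nx || yi < 0 || yi >= ny || zi < 0 || zi >= nz)
          v = background;
        else
          v = vol[(size_t)xi + (size_t)nx * ((size_t)yi + (size_t)ny * zi)];
        acc += wx * wy * wz * v;
      }
    }
  }
  return acc;
}

// Panoramic projection: P(c,z) = sum over midpoint samples t of
// X(r_c + t n(c), z) * dt, with t in [-w, w] (millimetres along the arch
// normal) and trilinear interpolation of X. Arch points/normals are in
// 0-based voxel coordinates of the axial plane; in-plane spacing must be
// isotropic (checked in R). Units of P: intensity * mm.
// [[Rcpp::export]]
NumericMatrix cpp_panoramic(const NumericVector& vol, const IntegerVector& dim,
                            const NumericMatrix& arch_pts,
                            const NumericMatrix& arch_nrm,
                            double w_mm, double spacing_xy, double dt_mm,
                            double background) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int C = arch_pts.nrow();
  NumericMatrix out(C, nz);
  if (w_mm <= 0) return out; // degenerate zero-length integral
  int K = std::max(1, (int)std::ceil(2.0 * w_mm / dt_mm));
  double step = 2.0 * w_mm / K;
  const double* v = REAL(vol);
  for (int c = 0; c < C; ++c) {
    double rx = arch_pts(c,0), ry = arch_pts(c,1);
    double nxv = arch_nrm(c,0), nyv = arch_nrm(c,1);
    for (int s = 0; s < K; ++s) {
      double t = -w_mm + (s + 0.5) * step;     // midpoint rule
      double px = rx + (t / spacing_xy) * nxv;
      double py = ry + (t / spacing_xy) * nyv;
      for (int z = 0; z < nz; ++z) {
        out(c, z) += sample_trilinear(v, nx, ny, nz, px, py, (double)z,
                                      background) * step;
      }
    }
  }
  return out;
}

// Project a labelled volume into panoramic space: for each label 1..nlabels,
// a logical C x nz mask marking panoramic pixels whose sampling segment
// passes through a voxel carrying that label (nearest-voxel lookup).
// [[Rcpp::export]]
List cpp_pano_label_masks(const IntegerVector& labels, const IntegerVector& dim,
                          const NumericMatrix& arch_pts,
                          const NumericMatrix& arch_nrm,
                          double w_mm, double spacing_xy, double dt_mm,
                          int nlabels) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int C = arch_pts.nrow();
  std::vector<LogicalMatrix> masks;
  masks.reserve(nlabels);
  for (int l = 0; l < nlabels; ++l) masks.emplace_back(C, nz);
  int K = std::max(1, (int)std::ceil(2.0 * w_mm / std::max(dt_mm, 1e-9)));
  double step = 2.0 * w_mm / K;
  const int* lab = INTEGER(labels);
  for (int c = 0; c < C; ++c) {
    double rx = arch_pts(c,0), ry = arch_pts(c,1);
    double nxv = arch_nrm(c,0), nyv = arch_nrm(c,1);
    for (int s = 0; s < K; ++s) {
      double t = -w_mm + (s + 0.5) * step;
      int px = (int)std::lround(rx + (t / spacing_xy) * nxv);
      int py = (int)std::lround(ry + (t / spacing_xy) * nyv);
      if (px < 0 || px >= nx || py < 0 || py >= ny) continue;
      for (int z = 0; z < nz; ++z) {
        int l = lab[(size_t)px + (size_t)nx * ((size_t)py + (size_t)ny * z)];
        if (l >= 1 && l <= nlabels) masks[l-1](c, z) = true;
      }
    }
  }
  List out(nlabels);
  for (int l = 0; l < nlabels; ++l) out[l] = masks[l];
  return out;
}

// Rasterize the dental phantom: analytic tooth solids along an arch, a
// bone band around the arch polyline, a soft-tissue ellipse cylinder, air
// elsewhere. A crown is a superellipsoid generalised cylinder whose radial
// profile r * s(theta) has an elliptical cross-section (minor axis factor
// ell_b, rotated by psi to follow the arch) modulated by a cuspal ripple
// (1 + cusp_amp * cos(cusp_n * theta + cusp_phase)); the root is a
// circular cone frustum.
// teeth columns: cx, cy, crown_r, exponent, crown_zlo, crown_zhi,
//                root_zlo, root_zhi, root_r_lo, root_r_hi, label,
//                psi, ell_b, cusp_amp, cusp_n, cusp_phase
// Returns intensities (double array) and per-voxel tooth labels (0 = none).
// [[Rcpp::export]]
List cpp_rasterize_phantom(const IntegerVector& dim, const NumericVector& spacing,
                           const NumericVector& origin,
                           const NumericMatrix& teeth,
                           const NumericMatrix& bone_polyline,
                           double bone_radius,
                           const NumericVector& bone_z_lower,
                           const NumericVector& bone_z_upper,
                           const NumericVector& soft_ellipse,
                           double teeth_hu, double bone_hu, double soft_hu,
                           double air_hu) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t ntot = (size_t)nx * ny * nz;
  NumericVector vol(ntot, air_hu);
  IntegerVector lab(ntot, 0);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double ox = origin[0], oy = origin[1], oz = origin[2];
  double* V = REAL(vol);
  int* L = INTEGER(lab);

  // soft tissue ellipse cylinder (full z)
  double ex = soft_ellipse[0], ey = soft_ellipse[1];
  double ea = soft_ellipse[2], eb = soft_ellipse[3];
  for (int j = 0; j < ny; ++j) {
    double wy = oy + sy * j;
    for (int i = 0; i < nx; ++i) {
      double wx = ox + sx * i;
      double u = (wx - ex) / ea, v = (wy - ey) / eb;
      if (u*u + v*v <= 1.0) {
        for (int k = 0; k < nz; ++k)
          V[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)] = soft_hu;
      }
    }
  }

  // axial distance field to the arch polyline, then bone band in root zones
  int nseg = bone_polyline.nrow() - 1;
  if (nseg > 0 && bone_radius > 0) {
    std::vector<double> dist2(nx * (size_t)ny,
                              std::numeric_limits<double>::infinity());
    for (int j = 0; j < ny; ++j) {
      double wy = oy + sy * j;
      for (int i = 0; i < nx; ++i) {
        double wx = ox + sx * i;
        double best = std::numeric_limits<double>::infinity();
        for (int s = 0; s < nseg; ++s) {
          double ax = bone_polyline(s,0), ay = bone_polyline(s,1);
          double bx = bone_polyline(s+1,0), by = bone_polyline(s+1,1);
          double dx = bx - ax, dy = by - ay;
          double len2 = dx*dx + dy*dy;
          double tt = len2 > 0 ? ((wx-ax)*dx + (wy-ay)*dy) / len2 : 0.0;
          tt = std::min(1.0, std::max(0.0, tt));
          double px = ax + tt*dx - wx, py = ay + tt*dy - wy;
          double d2 = px*px + py*py;
          if (d2 < best) best = d2;
        }
        dist2[(size_t)i + (size_t)nx * j] = best;
      }
    }
    double br2 = bone_radius * bone_radius;
    for (int k = 0; k < nz; ++k) {
      double wz = oz + sz * k;
      bool in_lower = wz >= bone_z_lower[0] && wz <= bone_z_lower[1];
      bool in_upper = wz >= bone_z_upper[0] && wz <= bone_z_upper[1];
      if (!in_lower && !in_upper) continue;
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          if (dist2[(size_t)i + (size_t)nx * j] <= br2)
            V[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)] = bone_hu;
    }
  }

  // teeth (crown + root), highest priority, carry labels
  for (int tth = 0; tth < teeth.nrow(); ++tth) {
    double cx = teeth(tth,0), cy = teeth(tth,1), cr = teeth(tth,2);
    double expo = teeth(tth,3);
    double czlo = teeth(tth,4), czhi = teeth(tth,5);
    double rzlo = teeth(tth,6), rzhi = teeth(tth,7);
    double rrlo = teeth(tth,8), rrhi = teeth(tth,9);
    int label = (int)teeth(tth,10);
    double psi = teeth(tth,11), ell_b = teeth(tth,12);
    double camp = teeth(tth,13), cn = teeth(tth,14), cph = teeth(tth,15);
    double zc = 0.5 * (czlo + czhi), hh = 0.5 * (czhi - czlo);
    double rmax = std::max(cr * (1.0 + camp), std::max(rrlo, rrhi));
    int i0 = std::max(0, (int)std::floor((cx - rmax - ox) / sx));
    int i1 = std::min(nx-1, (int)std::ceil((cx + rmax - ox) / sx));
    int j0 = std::max(0, (int)std::floor((cy - rmax - oy) / sy));
    int j1 = std::min(ny-1, (int)std::ceil((cy + rmax - oy) / sy));
    double zlo = std::min(czlo, rzlo), zhi = std::max(czhi, rzhi);
    int k0 = std::max(0, (int)std::floor((zlo - oz) / sz));
    int k1 = std::min(nz-1, (int)std::ceil((zhi - oz) / sz));
    // point-in-tooth test (crown generalised superellipsoid or root frustum)
    auto inside_tooth = [&](double wx, double wy, double wz) -> bool {
      double rho = std::hypot(wx - cx, wy - cy);
      if (wz >= czlo && wz <= czhi && hh > 0) {
        double th = std::atan2(wy - cy, wx - cx) - psi;
        double es = ell_b / std::sqrt(ell_b*ell_b*std::cos(th)*std::cos(th) +
                                      std::sin(th)*std::sin(th));
        double s = es * (1.0 + camp * std::cos(cn * th + cph));
        double a = rho / (cr * s), b = std::fabs(wz - zc) / hh;
        if (std::pow(a, expo) + std::pow(b, expo) <= 1.0) return true;
      }
      if (wz >= rzlo && wz <= rzhi && rzhi > rzlo) {
        double f = (wz - rzlo) / (rzhi - rzlo);
        double rr = rrlo + (rrhi - rrlo) * f;
        if (rho <= rr) return true;
      }
      return false;
    };
    // partial-volume rendering: voxel intensity blends the backdrop with
    // the tooth value by the occupancy fraction (3x3x3 subsampling), as
    // CT partial-volume averaging does; labels use majority occupancy
    const int SS = 3;
    for (int k = k0; k <= k1; ++k) {
      double wz = oz + sz * k;
      for (int j = j0; j <= j1; ++j) {
        double wy = oy + sy * j;
        for (int i = i0; i <= i1; ++i) {
          double wx = ox + sx * i;
          // cheap reject: outside the tooth's maximal radius by more than
          // a voxel diagonal
          double diag = std::sqrt(sx*sx + sy*sy + sz*sz);
          if (std::hypot(wx - cx, wy - cy) > rmax + diag) continue;
          int cnt = 0;
          for (int a = 0; a < SS; ++a)
            for (int b = 0; b < SS; ++b)
              for (int c = 0; c < SS; ++c) {
                double ux = wx + sx * ((a + 0.5) / SS - 0.5);
                double uy = wy + sy * ((b + 0.5) / SS - 0.5);
                double uz = wz + sz * ((c + 0.5) / SS - 0.5);
                if (inside_tooth(ux, uy, uz)) ++cnt;
              }
          if (cnt == 0) continue;
          double f = (double)cnt / (SS * SS * SS);
          size_t off = (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k);
          V[off] = V[off] * (1.0 - f) + teeth_hu * f;
          if (f >= 0.5) L[off] = label;
        }
      }
    }
  }
  vol.attr("dim") = dim;
  lab.attr("dim") = dim;
  return List::create(_["intensities"] = vol, _["labels"] = lab);
}
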