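#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <random>
using namespace Rcpp;

// Bowyer-Watson Delaunay triangulation in 2D with an alpha-complex area:
// the returned area is the total area of Delaunay triangles whose
// circumradius is at most alpha. Input degeneracies (grids of voxel centres
// are highly cocircular) are broken by a deterministic sub-micrometre
// jitter, which is negligible at millimetre scale.

struct Tri { int a, b, c; long double ccx, ccy, cr2; };

static bool circumcircle(const std::vector<long double>& X,
                         const std::vector<long double>& Y,
                         int a, int b, int c, Tri& t) {
  long double ax = X[a], ay = Y[a], bx = X[b], by = Y[b], cx = X[c], cy = Y[c];
  long double d = 2.0L * (ax*(by-cy) + bx*(cy-ay) + cx*(ay-by));
  if (std::fabs((double)d) < 1e-30) return false;
  long double a2 = ax*ax + ay*ay, b2 = bx*bx + by*by, c2 = cx*cx + cy*cy;
  t.ccx = (a2*(by-cy) + b2*(cy-ay) + c2*(ay-by)) / d;
  t.ccy = (a2*(cx-bx) + b2*(ax-cx) + c2*(bx-ax)) / d;
  long double dx = ax - t.ccx, dy = ay - t.ccy;
  t.cr2 = dx*dx + dy*dy;
  t.a = a; t.b = b; t.c = c;
  return true;
}

// [[Rcpp::export]]
double cpp_alpha_shape_area(const NumericMatrix& xy, double alpha) {
  int n0 = xy.nrow();
  if (n0 < 3) return 0.0;
  // deduplicate exact coincident points, then jitter deterministically
  std::map<std::pair<double,double>, int> seen;
  std::vector<long double> X, Y;
  std::mt19937 rng(987654321u);
  std::uniform_real_distribution<double> U(-5e-7, 5e-7);
  for (int i = 0; i < n0; ++i) {
    auto key = std::make_pair(xy(i,0), xy(i,1));
    if (seen.count(key)) { U(rng); U(rng); continue; } // keep jitter stream aligned
    seen[key] = 1;
    X.push_back((long double)xy(i,0) + U(rng));
    Y.push_back((long double)xy(i,1) + U(rng));
  }
  int n = (int)X.size();
  if (n < 3) return 0.0;
  // super-triangle
  long double xmin = X[0], xmax = X[0], ymin = Y[0], ymax = Y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, X[i]); xmax = std::max(xmax, X[i]);
    ymin = std::min(ymin, Y[i]); ymax = std::max(ymax, Y[i]);
  }
  long double span = std::max(xmax - xmin, ymax - ymin);
  if (span <= 0) return 0.0;
  long double cx = 0.5L*(xmin+xmax), cy = 0.5L*(ymin+ymax);
  X.push_back(cx - 30.0L*span); Y.push_back(cy - 10.0L*span);
  X.push_back(cx + 30.0L*span); Y.push_back(cy - 10.0L*span);
  X.push_back(cx);              Y.push_back(cy + 30.0L*span);
  int s0 = n, s1 = n+1, s2 = n+2;

  std::vector<Tri> tris;
  Tri st;
  if (!circumcircle(X, Y, s0, s1, s2, st)) return 0.0;
  tris.push_back(st);

  std::vector<int> bad;
  std::map<std::pair<int,int>, int> edges;
  for (int p = 0; p < n; ++p) {
    bad.clear();
    for (int t = 0; t < (int)tris.size(); ++t) {
      long double dx = X[p] - tris[t].ccx, dy = Y[p] - tris[t].ccy;
      if (dx*dx + dy*dy <= tris[t].cr2) bad.push_back(t);
    }
    if (bad.empty()) continue; // numerically lost point; safe to skip
    edges.clear();
    auto add_edge = [&](int u, int v) {
      auto key = std::minmax(u, v);
      edges[{key.first, key.second}] += 1;
    };
    for (int t : bad) {
      add_edge(tris[t].a, tris[t].b);
      add_edge(tris[t].b, tris[t].c);
      add_edge(tris[t].c, tris[t].a);
    }
    // remove bad triangles (descending order keeps indices valid)
    for (int i = (int)bad.size()-1; i >= 0; --i) {
      tris[bad[i]] = tris.back();
      tris.pop_back();
    }
    for (auto& e : edges) {
      if (e.second != 1) continue; // interior cavity edge
      Tri nt;
      if (circumcircle(X, Y, e.first.first, e.first.second, p, nt))
        tris.push_back(nt);
    }
  }

  long double a2 = (long double)alpha * alpha;
  long double area = 0.0L;
  for (const Tri& t : tris) {
    if (t.a >= n || t.b >= n || t.c >= n) continue; // touches super-triangle
    if (t.cr2 > a2) continue;
    long double ar = 0.5L * std::fabs((double)((X[t.b]-X[t.a])*(Y[t.c]-Y[t.a]) -
                                               (X[t.c]-X[t.a])*(Y[t.b]-Y[t.a])));
    area += ar;
  }
  return (double)area;
}
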