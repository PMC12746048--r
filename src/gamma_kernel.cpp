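#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bilinear interpolation on the evaluated grid at physical point (y, x).
// Returns false when the point lies outside the convex hull of pixel
// centers (such candidate positions are skipped in the search).
static inline bool interp(const NumericMatrix &v, double y0, double x0,
                          double dy, double dx, double y, double x,
                          double &out) {
  double gy = (y - y0) / dy;
  double gx = (x - x0) / dx;
  int nr = v.nrow(), nc = v.ncol();
  if (gy < 0.0 || gy > nr - 1 || gx < 0.0 || gx > nc - 1) return false;
  int r0 = std::min((int)std::floor(gy), nr - 2);
  int c0 = std::min((int)std::floor(gx), nc - 2);
  double fy = gy - r0, fx = gx - c0;
  out = (1 - fy) * (1 - fx) * v(r0, c0) + (1 - fy) * fx * v(r0, c0 + 1) +
        fy * (1 - fx) * v(r0 + 1, c0) + fy * fx * v(r0 + 1, c0 + 1);
  return true;
}

struct Offset {
  double dy, dx, dist;
};

// 2D gamma search. For each included reference point the gamma function is
// minimized over candidate positions on a disc of radius cap*dta around the
// point, visited in order of increasing distance so the scan can stop as
// soon as the distance term alone exceeds the running minimum. The
// evaluated dose is interpolated bilinearly at each candidate position.
// tol(i,j) is the absolute dose tolerance at reference point (i,j) (already
// global or local); gamma values above `cap` are reported as `cap`.
// Excluded points and points with no candidate inside the evaluated extent
// come back as NA.
// [[Rcpp::export]]
NumericMatrix gamma_search_cpp(NumericMatrix ref, double ry0, double rx0,
                               double rdy, double rdx, NumericMatrix eval,
                               double ey0, double ex0, double edy, double edx,
                               LogicalMatrix include, NumericMatrix tol,
                               double dta, double step, double cap) {
  int nr = ref.nrow(), nc = ref.ncol();
  NumericMatrix gamma(nr, nc);
  std::fill(gamma.begin(), gamma.end(), NA_REAL);

  double radius = cap * dta;
  int ksteps = (int)std::ceil(radius / step);
  std::vector<Offset> offs;
  offs.reserve((2 * ksteps + 1) * (2 * ksteps + 1));
  for (int i = -ksteps; i <= ksteps; ++i) {
    for (int j = -ksteps; j <= ksteps; ++j) {
      double dy = i * step, dx = j * step;
      double d = std::sqrt(dy * dy + dx * dx);
      if (d <= radius + 1e-12) offs.push_back({dy, dx, d});
    }
  }
  std::sort(offs.begin(), offs.end(),
            [](const Offset &a, const Offset &b) { return a.dist < b.dist; });

  for (int i = 0; i < nr; ++i) {
    double py = ry0 + i * rdy;
    for (int j = 0; j < nc; ++j) {
      if (!include(i, j)) continue;
      double px = rx0 + j * rdx;
      double dref = ref(i, j);
      double t = tol(i, j);
      double best = cap;
      double bdy = 0.0, bdx = 0.0;
      bool found = false;
      for (const Offset &o : offs) {
        double dterm = o.dist / dta;
        if (dterm >= best) break; // later offsets can only be worse
        double de;
        if (!interp(eval, ey0, ex0, edy, edx, py + o.dy, px + o.dx, de))
          continue;
        double dd = (de - dref) / t;
        double g = std::sqrt(dterm * dterm + dd * dd);
        if (g < best) {
          best = g;
          bdy = o.dy;
          bdx = o.dx;
        }
        found = true;
      }
      // local refinement around the best coarse offset: successively
      // halved 3x3 pattern searches polish the minimum of the (piecewise
      // smooth) gamma function well below the coarse sampling error
      if (found) {
        double h = step;
        for (int level = 0; level < 7; ++level) {
          h *= 0.5;
          bool improved = true;
          while (improved) {
            improved = false;
            for (int a = -1; a <= 1; ++a) {
              for (int b = -1; b <= 1; ++b) {
                if (a == 0 && b == 0) continue;
                double dy = bdy + a * h, dx = bdx + b * h;
                double d = std::sqrt(dy * dy + dx * dx);
                if (d >= radius) continue;
                double de;
                if (!interp(eval, ey0, ex0, edy, edx, py + dy, px + dx, de))
                  continue;
                double dd = (de - dref) / t;
                double dterm = d / dta;
                double g = std::sqrt(dterm * dterm + dd * dd);
                if (g < best - 1e-12) {
                  best = g;
                  bdy = dy;
                  bdx = dx;
                  improved = true;
                }
              }
            }
          }
        }
        gamma(i, j) = best;
      }
    }
  }
  return gamma;
}
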