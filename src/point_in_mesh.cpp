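#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Watertight-mesh point containment by ray casting.
//
// Primary ray is +z with a uniform (x,y) grid over triangle footprints so
// each query only visits nearby triangles. Queries whose ray passes within
// a relative tolerance of a triangle edge, or hits a near-vertical
// triangle, are re-cast with random directions (supplied by the caller so
// results are reproducible) against all triangles using Moller-Trumbore
// with strict interior tests.

static bool ray_hits(const double *o, const double *d,
                     const double *a, const double *b, const double *c,
                     double eps, bool &degenerate) {
  double e1[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double e2[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double p[3] = {d[1] * e2[2] - d[2] * e2[1],
                 d[2] * e2[0] - d[0] * e2[2],
                 d[0] * e2[1] - d[1] * e2[0]};
  double det = e1[0] * p[0] + e1[1] * p[1] + e1[2] * p[2];
  double scale = std::sqrt((e1[0]*e1[0]+e1[1]*e1[1]+e1[2]*e1[2]) *
                           (e2[0]*e2[0]+e2[1]*e2[1]+e2[2]*e2[2]));
  if (std::fabs(det) < 1e-9 * scale) { // ray (near-)parallel to the plane
    // harmless unless the ray runs within tolerance of the plane itself
    double nrm[3] = {e1[1] * e2[2] - e1[2] * e2[1],
                     e1[2] * e2[0] - e1[0] * e2[2],
                     e1[0] * e2[1] - e1[1] * e2[0]};
    double nlen = std::sqrt(nrm[0]*nrm[0] + nrm[1]*nrm[1] + nrm[2]*nrm[2]);
    double dist = std::fabs(nrm[0] * (o[0] - a[0]) + nrm[1] * (o[1] - a[1]) +
                            nrm[2] * (o[2] - a[2]));
    if (nlen > 0 && dist < 1e-8 * std::sqrt(scale) * nlen) degenerate = true;
    return false;
  }
  double inv = 1.0 / det;
  double tv[3] = {o[0] - a[0], o[1] - a[1], o[2] - a[2]};
  double u = (tv[0] * p[0] + tv[1] * p[1] + tv[2] * p[2]) * inv;
  double q[3] = {tv[1] * e1[2] - tv[2] * e1[1],
                 tv[2] * e1[0] - tv[0] * e1[2],
                 tv[0] * e1[1] - tv[1] * e1[0]};
  double v = (d[0] * q[0] + d[1] * q[1] + d[2] * q[2]) * inv;
  double t = (e2[0] * q[0] + e2[1] * q[1] + e2[2] * q[2]) * inv;
  if (u > eps && v > eps && (u + v) < 1.0 - eps && t > eps) return true;
  // near an edge/vertex or the query plane: ambiguous crossing
  if (u > -eps && v > -eps && (u + v) < 1.0 + eps && t > -eps) degenerate = true;
  return false;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix V, IntegerMatrix F,
                                 NumericMatrix P, NumericMatrix fallback_dirs) {
  const int nf = F.nrow(), np = P.nrow();
  std::vector<double> ax(nf), ay(nf), az(nf), bx(nf), by(nf), bz(nf),
      cx(nf), cy(nf), cz(nf);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf,
         zmax = R_NegInf, zmin = R_PosInf;
  for (int i = 0; i < nf; ++i) {
    int i1 = F(i, 0) - 1, i2 = F(i, 1) - 1, i3 = F(i, 2) - 1;
    ax[i] = V(i1, 0); ay[i] = V(i1, 1); az[i] = V(i1, 2);
    bx[i] = V(i2, 0); by[i] = V(i2, 1); bz[i] = V(i2, 2);
    cx[i] = V(i3, 0); cy[i] = V(i3, 1); cz[i] = V(i3, 2);
    xmin = std::min(xmin, std::min(ax[i], std::min(bx[i], cx[i])));
    xmax = std::max(xmax, std::max(ax[i], std::max(bx[i], cx[i])));
    ymin = std::min(ymin, std::min(ay[i], std::min(by[i], cy[i])));
    ymax = std::max(ymax, std::max(ay[i], std::max(by[i], cy[i])));
    zmin = std::min(zmin, std::min(az[i], std::min(bz[i], cz[i])));
    zmax = std::max(zmax, std::max(az[i], std::max(bz[i], cz[i])));
  }
  double diam = std::max(xmax - xmin, std::max(ymax - ymin, zmax - zmin));
  if (diam <= 0.0) diam = 1.0;
  const double eps = 1e-10;

  // (x,y) occupancy grid over triangle footprints
  int ng = std::max(8, (int)std::floor(std::sqrt((double)nf)));
  ng = std::min(ng, 512);
  double gx = (xmax - xmin) / ng, gy = (ymax - ymin) / ng;
  if (gx <= 0) gx = 1; if (gy <= 0) gy = 1;
  std::vector<std::vector<int> > cells((size_t)ng * ng);
  for (int i = 0; i < nf; ++i) {
    double txmin = std::min(ax[i], std::min(bx[i], cx[i]));
    double txmax = std::max(ax[i], std::max(bx[i], cx[i]));
    double tymin = std::min(ay[i], std::min(by[i], cy[i]));
    double tymax = std::max(ay[i], std::max(by[i], cy[i]));
    int c0 = std::max(0, std::min(ng - 1, (int)((txmin - xmin) / gx)));
    int c1 = std::max(0, std::min(ng - 1, (int)((txmax - xmin) / gx)));
    int r0 = std::max(0, std::min(ng - 1, (int)((tymin - ymin) / gy)));
    int r1 = std::max(0, std::min(ng - 1, (int)((tymax - ymin) / gy)));
    for (int r = r0; r <= r1; ++r)
      for (int c = c0; c <= c1; ++c)
        cells[(size_t)r * ng + c].push_back(i);
  }

  const double zdir[3] = {0.0, 0.0, 1.0};
  LogicalVector out(np);
  for (int pi = 0; pi < np; ++pi) {
    double o[3] = {P(pi, 0), P(pi, 1), P(pi, 2)};
    if (o[0] < xmin || o[0] > xmax || o[1] < ymin || o[1] > ymax ||
        o[2] < zmin || o[2] > zmax) {
      out[pi] = false;
      continue;
    }
    int c = std::max(0, std::min(ng - 1, (int)((o[0] - xmin) / gx)));
    int r = std::max(0, std::min(ng - 1, (int)((o[1] - ymin) / gy)));
    const std::vector<int> &cand = cells[(size_t)r * ng + c];
    int crossings = 0;
    bool degen = false;
    for (size_t k = 0; k < cand.size() && !degen; ++k) {
      int i = cand[k];
      double a[3] = {ax[i], ay[i], az[i]}, b[3] = {bx[i], by[i], bz[i]},
             cc[3] = {cx[i], cy[i], cz[i]};
      if (ray_hits(o, zdir, a, b, cc, eps, degen)) ++crossings;
    }
    if (!degen) {
      out[pi] = (crossings % 2) == 1;
      continue;
    }
    // fallback: random-direction rays against all triangles
    bool done = false;
    for (int di = 0; di < fallback_dirs.nrow() && !done; ++di) {
      double d[3] = {fallback_dirs(di, 0), fallback_dirs(di, 1),
                     fallback_dirs(di, 2)};
      crossings = 0;
      degen = false;
      for (int i = 0; i < nf && !degen; ++i) {
        double a[3] = {ax[i], ay[i], az[i]}, b[3] = {bx[i], by[i], bz[i]},
               cc[3] = {cx[i], cy[i], cz[i]};
        if (ray_hits(o, d, a, b, cc, eps, degen)) ++crossings;
      }
      if (!degen) {
        out[pi] = (crossings % 2) == 1;
        done = true;
      }
    }
    if (!done) out[pi] = false; // exhausted fallback directions (no clean ray)
  }
  return out;
}
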