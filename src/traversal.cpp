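#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Shared Amanatides & Woo incremental traversal of a semi-infinite ray
// (t >= 0 from src) through an axis-aligned voxel grid.  Calls visit(i,j,k,
// tA, tB) for every voxel crossed with positive parametric extent [tA,tB],
// in order along the ray, clipped to t <= tStop.
template <typename F>
static void traverse(const double src[3], const double dir[3],
                     const int shape[3], const double spacing[3],
                     const double origin[3], double tStop, F visit) {
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = origin[k] - spacing[k] / 2.0;
    hi[k] = origin[k] + (shape[k] - 0.5) * spacing[k];
  }
  double t0 = 0.0, t1 = tStop;
  for (int k = 0; k < 3; ++k) {
    if (std::fabs(dir[k]) < 1e-300) {
      if (src[k] < lo[k] || src[k] > hi[k]) return;
    } else {
      double ta = (lo[k] - src[k]) / dir[k];
      double tb = (hi[k] - src[k]) / dir[k];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (t1 <= t0) return;

  int idx[3], step[3];
  double tMax[3], tDelta[3];
  const double inf = std::numeric_limits<double>::infinity();
  // entry point nudged inside to get a well-defined starting voxel
  double tcur = t0;
  for (int k = 0; k < 3; ++k) {
    double p = src[k] + (t0 + 1e-12) * dir[k];
    int i = (int)std::floor((p - lo[k]) / spacing[k]);
    if (i < 0) i = 0;
    if (i > shape[k] - 1) i = shape[k] - 1;
    idx[k] = i;
    if (dir[k] > 0) {
      step[k] = 1;
      tMax[k] = (lo[k] + (i + 1) * spacing[k] - src[k]) / dir[k];
      tDelta[k] = spacing[k] / dir[k];
    } else if (dir[k] < 0) {
      step[k] = -1;
      tMax[k] = (lo[k] + i * spacing[k] - src[k]) / dir[k];
      tDelta[k] = -spacing[k] / dir[k];
    } else {
      step[k] = 0;
      tMax[k] = inf;
      tDelta[k] = inf;
    }
  }
  while (tcur < t1 - 1e-12) {
    int ax = 0;
    if (tMax[1] < tMax[ax]) ax = 1;
    if (tMax[2] < tMax[ax]) ax = 2;
    double tnext = tMax[ax];
    if (tnext > t1) tnext = t1;
    if (tnext > tcur) visit(idx[0], idx[1], idx[2], tcur, tnext);
    if (tMax[ax] >= t1) break;
    tcur = tMax[ax];
    tMax[ax] += tDelta[ax];
    idx[ax] += step[ax];
    if (idx[ax] < 0 || idx[ax] >= shape[ax]) break;
  }
}

// [[Rcpp::export]]
List cpp_trace_ray(NumericVector source, NumericVector direction,
                   IntegerVector shape, NumericVector spacing,
                   NumericVector origin) {
  double src[3], dir[3], sp[3], org[3];
  int sh[3];
  for (int k = 0; k < 3; ++k) {
    src[k] = source[k]; dir[k] = direction[k];
    sp[k] = spacing[k]; org[k] = origin[k]; sh[k] = shape[k];
  }
  std::vector<int> vi, vj, vk;
  std::vector<double> len;
  const double inf = std::numeric_limits<double>::infinity();
  traverse(src, dir, sh, sp, org, inf,
           [&](int i, int j, int k, double ta, double tb) {
             double l = tb - ta;
             if (l > 1e-9) {  // grazing contacts treated as not crossed
               vi.push_back(i); vj.push_back(j); vk.push_back(k);
               len.push_back(l);
             }
           });
  int n = (int)len.size();
  IntegerMatrix index(n, 3);
  NumericVector length(n);
  for (int r = 0; r < n; ++r) {
    index(r, 0) = vi[r]; index(r, 1) = vj[r]; index(r, 2) = vk[r];
    length[r] = len[r];
  }
  return List::create(_["index"] = index, _["length"] = length);
}

static double bilinear(const NumericMatrix &f, double gx, double gy) {
  int nx = f.nrow(), ny = f.ncol();
  if (gx < 0 || gy < 0 || gx > nx - 1 || gy > ny - 1) return 0.0;
  int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy);
  if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
  if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
  double fx = gx - i0, fy = gy - j0;
  if (nx == 1) { i0 = 0; fx = 0; }
  if (ny == 1) { j0 = 0; fy = 0; }
  int i1 = i0 + (nx > 1), j1 = j0 + (ny > 1);
  return (1 - fx) * (1 - fy) * f(i0, j0) + fx * (1 - fy) * f(i1, j0) +
         (1 - fx) * fy * f(i0, j1) + fx * fy * f(i1, j1);
}

// Primary-beam dose for one beam: for every voxel, sample the fluence at the
// voxel's divergent projection onto the isocenter plane, attenuate by the
// radiological path length from the volume entry to the voxel, and apply the
// inverse-square factor (SAD/(SAD-z))^2 relative to the isocenter.
// axes = 3x3 matrix whose columns are the beam frame axes (ex ey ez) in
// world coordinates.
// [[Rcpp::export]]
NumericVector cpp_dose_beam(NumericVector density, IntegerVector shape,
                            NumericVector spacing, NumericVector origin,
                            NumericMatrix axes, NumericVector isocenter,
                            double SAD, NumericMatrix intensity,
                            NumericVector pspacing, NumericVector porigin,
                            double mu) {
  int sh[3];
  double sp[3], org[3];
  for (int k = 0; k < 3; ++k) { sh[k] = shape[k]; sp[k] = spacing[k]; org[k] = origin[k]; }
  const int nx = sh[0], ny = sh[1], nz = sh[2];
  NumericVector dose((R_xlen_t)nx * ny * nz);
  double ex[3], ey[3], ez[3], srcw[3];
  for (int k = 0; k < 3; ++k) {
    ex[k] = axes(k, 0); ey[k] = axes(k, 1); ez[k] = axes(k, 2);
    srcw[k] = isocenter[k] + SAD * ez[k];
  }
  R_xlen_t lin = 0;
  for (int k = 0; k < nz; ++k) {
    double cz = org[2] + k * sp[2];
    for (int j = 0; j < ny; ++j) {
      double cy = org[1] + j * sp[1];
      for (int i = 0; i < nx; ++i, ++lin) {
        double cx = org[0] + i * sp[0];
        double d0 = cx - isocenter[0], d1 = cy - isocenter[1], d2 = cz - isocenter[2];
        double bz = d0 * ez[0] + d1 * ez[1] + d2 * ez[2];
        if (bz >= SAD)
          stop("cpp_dose_beam: voxel at or behind the source (z >= SAD)");
        double bx = d0 * ex[0] + d1 * ex[1] + d2 * ex[2];
        double by = d0 * ey[0] + d1 * ey[1] + d2 * ey[2];
        double mag = SAD / (SAD - bz);
        double gx = (bx * mag - porigin[0]) / pspacing[0];
        double gy = (by * mag - porigin[1]) / pspacing[1];
        double flu = bilinear(intensity, gx, gy);
        if (flu <= 0) continue;
        double att = 1.0;
        if (mu > 0) {
          double dir[3];
          double tvox = 0.0;
          dir[0] = cx - srcw[0]; dir[1] = cy - srcw[1]; dir[2] = cz - srcw[2];
          tvox = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] + dir[2] * dir[2]);
          for (int a = 0; a < 3; ++a) dir[a] /= tvox;
          double rad = 0.0;
          traverse(srcw, dir, sh, sp, org, tvox,
                   [&](int ii, int jj, int kk, double ta, double tb) {
                     rad += density[(R_xlen_t)ii + nx * ((R_xlen_t)jj + (R_xlen_t)ny * kk)] * (tb - ta);
                   });
          att = std::exp(-mu * rad);
        }
        dose[lin] = flu * att * mag * mag;
      }
    }
  }
  return dose;
}
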