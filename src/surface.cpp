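#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline R_xlen_t lin(int z, int y, int x, int nz, int ny) {
  return z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
}

// Trilinear interpolation; returns false if the 8-cell support leaves the
// grid or the domain (profiles truncate at the domain edge).
static bool trilin(const NumericVector& vol, const IntegerVector& domain,
                   int nz, int ny, int nx,
                   double z, double y, double x, double& val) {
  int z0 = (int)std::floor(z), y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  if (z0 < 0 || y0 < 0 || x0 < 0 || z0 + 1 >= nz || y0 + 1 >= ny || x0 + 1 >= nx)
    return false;
  double fz = z - z0, fy = y - y0, fx = x - x0;
  double acc = 0;
  for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dx = 0; dx <= 1; ++dx) {
        R_xlen_t j = lin(z0 + dz, y0 + dy, x0 + dx, nz, ny);
        if (!domain[j]) return false;
        double w = (dz ? fz : 1 - fz) * (dy ? fy : 1 - fy) * (dx ? fx : 1 - fx);
        acc += w * vol[j];
      }
  val = acc;
  return true;
}

// Gradient-guided boundary relocation. For each boundary voxel of the
// initial thresholded mask, the smoothed gray profile is sampled along the
// local gradient direction over +/- searchDist voxels (step 0.5) and the
// boundary is moved to the position of maximum gradient magnitude, with an
// optional three-point parabolic sub-sample refinement. Voxels between the
// old and the new boundary are reclassified; ties resolve to the position
// closest to the initial boundary. materialBrighter records which side of
// the edge is material.
// [[Rcpp::export(name = ".refine_surface_cpp")]]
IntegerVector refine_surface_cpp(NumericVector smooth, IntegerVector initMask,
                                 IntegerVector domain, IntegerVector dims,
                                 IntegerMatrix boundary, int searchDist,
                                 bool materialBrighter, bool subvoxel) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector mask = clone(initMask);
  const double step = 0.5;
  const int nsamp = (int)(2 * searchDist / step) + 1; // t = -L .. L
  std::vector<double> prof(nsamp), grad(nsamp);
  std::vector<bool> ok(nsamp);

  for (int b = 0; b < boundary.nrow(); ++b) {
    int bz = boundary(b, 0), by = boundary(b, 1), bx = boundary(b, 2);
    // central-difference gradient of the smoothed volume at the voxel
    auto at = [&](int z, int y, int x, double& v) -> bool {
      if (z < 0 || y < 0 || x < 0 || z >= nz || y >= ny || x >= nx)
        return false;
      R_xlen_t j = lin(z, y, x, nz, ny);
      if (!domain[j]) return false;
      v = smooth[j];
      return true;
    };
    double vzp, vzm, vyp, vym, vxp, vxm;
    if (!at(bz + 1, by, bx, vzp) || !at(bz - 1, by, bx, vzm) ||
        !at(bz, by + 1, bx, vyp) || !at(bz, by - 1, bx, vym) ||
        !at(bz, by, bx + 1, vxp) || !at(bz, by, bx - 1, vxm))
      continue; // keep initial classification at grid/domain edge
    double gz = (vzp - vzm) / 2, gy = (vyp - vym) / 2, gx = (vxp - vxm) / 2;
    double gn = std::sqrt(gz * gz + gy * gy + gx * gx);
    if (gn < 1e-12) continue; // flat: keep initial classification
    gz /= gn; gy /= gn; gx /= gn; // unit vector toward brighter grays

    // profile along the gradient direction, truncated at domain/grid edge
    int i0 = (nsamp - 1) / 2; // index of t = 0
    int lo = i0, hi = i0;
    for (int i = 0; i < nsamp; ++i) {
      double t = (i - i0) * step;
      double v;
      ok[i] = trilin(smooth, domain, nz, ny, nx,
                     bz + t * gz, by + t * gy, bx + t * gx, v);
      prof[i] = ok[i] ? v : 0.0;
    }
    while (lo > 0 && ok[lo - 1]) --lo;
    while (hi < nsamp - 1 && ok[hi + 1]) ++hi;
    if (hi - lo < 2) continue;

    // gradient magnitude along the profile (central differences)
    for (int i = lo + 1; i < hi; ++i)
      grad[i] = std::fabs(prof[i + 1] - prof[i - 1]) / (2 * step);
    int best = -1;
    for (int i = lo + 1; i < hi; ++i) {
      if (best < 0 || grad[i] > grad[best] + 1e-12 ||
          (std::fabs(grad[i] - grad[best]) <= 1e-12 &&
           std::abs(i - i0) < std::abs(best - i0)))
        best = i;
    }
    if (best < 0) continue;
    double tstar = (best - i0) * step;
    if (subvoxel && best > lo + 1 && best < hi - 1) {
      double a = grad[best - 1], bb = grad[best], c = grad[best + 1];
      double den = a - 2 * bb + c;
      if (std::fabs(den) > 1e-12) {
        double delta = 0.5 * (a - c) / den;
        if (delta > -1 && delta < 1) tstar += delta * step;
      }
    }

    // reclassify voxel centers between the old boundary (t = 0) and the
    // relocated edge (t = tstar); t > tstar is the brighter side
    double tlo = std::min(0.0, tstar), thi = std::max(0.0, tstar);
    for (int t = (int)std::floor(tlo); t <= (int)std::ceil(thi); ++t) {
      int pz = (int)std::lround(bz + t * gz);
      int py = (int)std::lround(by + t * gy);
      int px = (int)std::lround(bx + t * gx);
      if (pz < 0 || py < 0 || px < 0 || pz >= nz || py >= ny || px >= nx)
        continue;
      R_xlen_t j = lin(pz, py, px, nz, ny);
      if (!domain[j]) continue;
      bool brighterSide = t > tstar;
      mask[j] = (brighterSide == materialBrighter) ? 1 : 0;
    }
  }
  // clamp to domain
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  for (R_xlen_t i = 0; i < n; ++i) if (!domain[i]) mask[i] = 0;
  return mask;
}
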