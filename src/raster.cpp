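#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Supersampled rasterization of tapering tubes. segs rows are
// (p0z, p0y, p0x, p1z, p1y, p1x, r0, r1) in voxel units, 0-based
// continuous coordinates with radii in voxels. For every voxel, counts
// how many of factor^3 regularly spaced sub-samples fall inside at least
// one tube segment (point-to-segment distance <= linearly interpolated
// radius). A voxel is foreground when at least half the sub-samples are
// inside; the caller applies that threshold.
// [[Rcpp::export(name = ".raster_tubes_cpp")]]
IntegerVector raster_tubes_cpp(IntegerVector dims, NumericMatrix segs,
                               int factor) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector count(n);
  const int noff = factor * factor * factor;
  std::vector<double> offs(noff * 3);
  {
    int k = 0;
    for (int a = 0; a < factor; ++a)
      for (int b = 0; b < factor; ++b)
        for (int c = 0; c < factor; ++c) {
          offs[k * 3 + 0] = (a - (factor - 1) / 2.0) / factor;
          offs[k * 3 + 1] = (b - (factor - 1) / 2.0) / factor;
          offs[k * 3 + 2] = (c - (factor - 1) / 2.0) / factor;
          ++k;
        }
  }
  // stamp array avoids double-counting a sub-sample covered by several
  // segments: one pass per sub-sample offset
  std::vector<int> stamp(n, -1);

  for (int k = 0; k < noff; ++k) {
    double ez = offs[k * 3], ey = offs[k * 3 + 1], ex = offs[k * 3 + 2];
    for (int s = 0; s < segs.nrow(); ++s) {
      double p0z = segs(s, 0), p0y = segs(s, 1), p0x = segs(s, 2);
      double p1z = segs(s, 3), p1y = segs(s, 4), p1x = segs(s, 5);
      double r0 = segs(s, 6), r1 = segs(s, 7);
      double rmax = std::max(r0, r1) + 1.0;
      int zlo = std::max(0, (int)std::floor(std::min(p0z, p1z) - rmax));
      int zhi = std::min(nz - 1, (int)std::ceil(std::max(p0z, p1z) + rmax));
      int ylo = std::max(0, (int)std::floor(std::min(p0y, p1y) - rmax));
      int yhi = std::min(ny - 1, (int)std::ceil(std::max(p0y, p1y) + rmax));
      int xlo = std::max(0, (int)std::floor(std::min(p0x, p1x) - rmax));
      int xhi = std::min(nx - 1, (int)std::ceil(std::max(p0x, p1x) + rmax));
      double vz = p1z - p0z, vy = p1y - p0y, vx = p1x - p0x;
      double L2 = vz * vz + vy * vy + vx * vx;
      for (int x = xlo; x <= xhi; ++x)
        for (int y = ylo; y <= yhi; ++y)
          for (int z = zlo; z <= zhi; ++z) {
            R_xlen_t j = z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
            if (stamp[j] == k) continue;
            double qz = z + ez - p0z, qy = y + ey - p0y, qx = x + ex - p0x;
            double t = L2 > 0 ? (qz * vz + qy * vy + qx * vx) / L2 : 0.0;
            if (t < 0) t = 0; else if (t > 1) t = 1;
            double dz = qz - t * vz, dy = qy - t * vy, dx = qx - t * vx;
            double r = r0 + (r1 - r0) * t;
            if (dz * dz + dy * dy + dx * dx <= r * r) {
              stamp[j] = k;
              ++count[j];
            }
          }
    }
  }
  return count;
}

// Rasterize axis-aligned ellipsoids at voxel centres. Rows of ell are
// (cz, cy, cx, az, ay, ax) in 0-based voxel units (centres, semi-axes).
// [[Rcpp::export(name = ".raster_ellipsoids_cpp")]]
LogicalVector raster_ellipsoids_cpp(IntegerVector dims, NumericMatrix ell) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector out(n);
  for (int s = 0; s < ell.nrow(); ++s) {
    double cz = ell(s, 0), cy = ell(s, 1), cx = ell(s, 2);
    double az = ell(s, 3), ay = ell(s, 4), ax = ell(s, 5);
    int zlo = std::max(0, (int)std::ceil(cz - az));
    int zhi = std::min(nz - 1, (int)std::floor(cz + az));
    int ylo = std::max(0, (int)std::ceil(cy - ay));
    int yhi = std::min(ny - 1, (int)std::floor(cy + ay));
    int xlo = std::max(0, (int)std::ceil(cx - ax));
    int xhi = std::min(nx - 1, (int)std::floor(cx + ax));
    for (int x = xlo; x <= xhi; ++x) {
      double fx = (x - cx) / ax;
      for (int y = ylo; y <= yhi; ++y) {
        double fy = (y - cy) / ay;
        double rem = 1.0 - fx * fx - fy * fy;
        if (rem < 0) continue;
        for (int z = zlo; z <= zhi; ++z) {
          double fz = (z - cz) / az;
          if (fz * fz <= rem)
            out[z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = true;
        }
      }
    }
  }
  return out;
}
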