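#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Local thickness in the inscribed-sphere sense: for each foreground voxel
// the diameter (voxel units) of the largest sphere fully contained in the
// mask that covers the voxel. Computed by painting spheres centred at
// distance-ridge voxels in decreasing radius order; the inscribed radius at
// a voxel is its Euclidean distance to the nearest background voxel centre
// minus 0.5 (the surface is taken half a voxel beyond foreground centres).
// [[Rcpp::export(name = ".local_thickness_cpp")]]
NumericVector local_thickness_cpp(IntegerVector mask, IntegerVector dims,
                                  NumericVector edt) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector th(n);

  struct Cand { double r; R_xlen_t idx; };
  std::vector<Cand> cand;
  cand.reserve(1024);

  // a centre q is redundant when some neighbour's sphere contains q's
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    double rq = edt[i] - 0.5;
    if (rq < 0.5) rq = 0.5;
    int zz = (int)(i % nz);
    R_xlen_t rest = i / nz;
    int yy = (int)(rest % ny);
    int xx = (int)(rest / ny);
    bool redundant = false;
    for (int dz = -1; dz <= 1 && !redundant; ++dz)
      for (int dy = -1; dy <= 1 && !redundant; ++dy)
        for (int dx = -1; dx <= 1 && !redundant; ++dx) {
          if (!dz && !dy && !dx) continue;
          int z2 = zz + dz, y2 = yy + dy, x2 = xx + dx;
          if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
            continue;
          R_xlen_t j = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
          if (!mask[j]) continue;
          double rn = edt[j] - 0.5;
          double dd = std::sqrt((double)(dz * dz + dy * dy + dx * dx));
          if (rn >= rq + dd - 1e-9) redundant = true;
        }
    if (!redundant) cand.push_back({rq, i});
  }
  std::sort(cand.begin(), cand.end(),
            [](const Cand& a, const Cand& b) { return a.r > b.r; });

  // a sphere of radius r covers a voxel when it overlaps the voxel cube,
  // approximated as centre distance <= r + 0.5; this lets the maximal
  // sphere of a digital tube reach the outermost surface ring
  for (const Cand& c : cand) {
    double r = c.r;
    double d = 2 * r;
    int zz = (int)(c.idx % nz);
    R_xlen_t rest = c.idx / nz;
    int yy = (int)(rest % ny);
    int xx = (int)(rest / ny);
    int ri = (int)std::floor(r + 0.5 + 1e-9);
    double r2 = (r + 0.5) * (r + 0.5) + 1e-9;
    for (int dz = -ri; dz <= ri; ++dz) {
      int z2 = zz + dz;
      if (z2 < 0 || z2 >= nz) continue;
      for (int dy = -ri; dy <= ri; ++dy) {
        int y2 = yy + dy;
        if (y2 < 0 || y2 >= ny) continue;
        for (int dx = -ri; dx <= ri; ++dx) {
          int x2 = xx + dx;
          if (x2 < 0 || x2 >= nx) continue;
          if (dz * dz + dy * dy + dx * dx > r2) continue;
          R_xlen_t j = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
          if (mask[j] && th[j] < d) th[j] = d;
        }
      }
    }
  }
  return th;
}
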