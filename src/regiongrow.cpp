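#include <Rcpp.h>
#include <deque>
#include <cmath>
using namespace Rcpp;

// Gray-value flood fill (26-connectivity) from seed voxels. Non-adaptive:
// the reference is the fixed mean of the seed gray values. Adaptive: the
// reference is the running mean of all accepted voxels, updated as each
// voxel is accepted (breadth-first order, deterministic). Growth is
// confined to the inclusive box (z0,z1,y0,y1,x0,x1), 0-based.
// [[Rcpp::export(name = ".region_grow_cpp")]]
LogicalVector region_grow_cpp(NumericVector vol, IntegerVector dims,
                              IntegerMatrix seeds, double tol,
                              IntegerVector box, bool adaptive) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector out(n);
  const int z0 = box[0], z1 = box[1], y0 = box[2], y1 = box[3],
            x0 = box[4], x1 = box[5];

  double ref = 0;
  for (int s = 0; s < seeds.nrow(); ++s) {
    R_xlen_t j = seeds(s, 0) +
      (R_xlen_t)nz * (seeds(s, 1) + (R_xlen_t)ny * seeds(s, 2));
    ref += vol[j];
  }
  ref /= seeds.nrow();
  double sum = 0;
  R_xlen_t cnt = 0;

  std::deque<R_xlen_t> q;
  for (int s = 0; s < seeds.nrow(); ++s) {
    R_xlen_t j = seeds(s, 0) +
      (R_xlen_t)nz * (seeds(s, 1) + (R_xlen_t)ny * seeds(s, 2));
    if (!out[j]) {
      out[j] = true;
      sum += vol[j];
      ++cnt;
      q.push_back(j);
    }
  }
  if (adaptive) ref = sum / cnt;

  while (!q.empty()) {
    R_xlen_t cur = q.front(); q.pop_front();
    int zz = (int)(cur % nz);
    R_xlen_t rest = cur / nz;
    int yy = (int)(rest % ny);
    int xx = (int)(rest / ny);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dz && !dy && !dx) continue;
          int z2 = zz + dz, y2 = yy + dy, x2 = xx + dx;
          if (z2 < z0 || z2 > z1 || y2 < y0 || y2 > y1 ||
              x2 < x0 || x2 > x1)
            continue;
          R_xlen_t j = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
          if (out[j]) continue;
          if (std::fabs(vol[j] - ref) <= tol) {
            out[j] = true;
            q.push_back(j);
            if (adaptive) {
              sum += vol[j];
              ++cnt;
              ref = sum / cnt;
            }
          }
        }
  }
  return out;
}
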