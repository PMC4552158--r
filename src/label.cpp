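#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Neighborhood offsets for 6/18/26 connectivity in (z, y, x) order.
static int build_offsets(int connectivity, int off[][3]) {
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off[n][0] = dz; off[n][1] = dy; off[n][2] = dx;
        ++n;
      }
  return n;
}

// Connected-component labels (0 = background), breadth-first flood fill.
// Labels are assigned in raster-scan order of the first voxel reached,
// hence contiguous from 1 and deterministic.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(IntegerVector mask, IntegerVector dims,
                          int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n);
  int off[26][3];
  int noff = build_offsets(connectivity, off);

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int zz = (int)(cur % nz);
      R_xlen_t rest = cur / nz;
      int yy = (int)(rest % ny);
      int xx = (int)(rest / ny);
      for (int k = 0; k < noff; ++k) {
        int z2 = zz + off[k][0], y2 = yy + off[k][1], x2 = xx + off[k][2];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
          continue;
        R_xlen_t j = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
        if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}

// Foreground voxels with at least one background neighbor under the stated
// connectivity; voxels beyond the grid edge count as background.
// [[Rcpp::export(name = ".boundary3d_cpp")]]
LogicalVector boundary3d_cpp(IntegerVector mask, IntegerVector dims,
                             int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector out(n);
  int off[26][3];
  int noff = build_offsets(connectivity, off);

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int zz = (int)(i % nz);
    R_xlen_t rest = i / nz;
    int yy = (int)(rest % ny);
    int xx = (int)(rest / ny);
    bool b = false;
    for (int k = 0; k < noff && !b; ++k) {
      int z2 = zz + off[k][0], y2 = yy + off[k][1], x2 = xx + off[k][2];
      if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) {
        b = true;
      } else {
        R_xlen_t j = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
        if (!mask[j]) b = true;
      }
    }
    out[i] = b;
  }
  return out;
}

// Foreground voxels with at least one neighbor that is inside the domain
// but outside the mask; used to find the refinable part of a surface
// (grid edges and domain edges are not refinable boundaries).
// [[Rcpp::export(name = ".boundary_in_domain_cpp")]]
LogicalVector boundary_in_domain_cpp(IntegerVector mask, IntegerVector domain,
                                     IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector out(n);
  int off[26][3];
  int noff = build_offsets(connectivity, off);

  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int zz = (int)(i % nz);
    R_xlen_t rest = i / nz;
    int yy = (int)(rest % ny);
    int xx = (int)(rest / ny);
    bool b = false;
    for (int k = 0; k < noff && !b; ++k) {
      int z2 = zz + off[k][0], y2 = yy + off[k][1], x2 = xx + off[k][2];
      if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
        continue;
      R_xlen_t j = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
      if (domain[j] && !mask[j]) b = true;
    }
    out[i] = b;
  }
  return out;
}
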