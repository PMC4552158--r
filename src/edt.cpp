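#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable lower-envelope-of-parabolas pass per axis on squared distances.

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Distance (in voxel units) from every voxel to the nearest feature voxel
// (mask != 0). Feature voxels get 0.
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(IntegerVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double INF = 1e20;
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis z (stride 1)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int zz = 0; zz < nz; ++zz) f[zz] = out[base + zz];
      dt1d(f, d, v, z, nz);
      for (int zz = 0; zz < nz; ++zz) out[base + zz] = d[zz];
    }
  // axis y (stride nz)
  for (int x = 0; x < nx; ++x)
    for (int zz = 0; zz < nz; ++zz) {
      R_xlen_t base = zz + (R_xlen_t)nz * ny * x;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)nz * y];
      dt1d(f, d, v, z, ny);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)nz * y] = d[y];
    }
  // axis x (stride nz*ny)
  R_xlen_t sx = (R_xlen_t)nz * ny;
  for (int y = 0; y < ny; ++y)
    for (int zz = 0; zz < nz; ++zz) {
      R_xlen_t base = zz + (R_xlen_t)nz * y;
      for (int x = 0; x < nx; ++x) f[x] = out[base + sx * x];
      dt1d(f, d, v, z, nx);
      for (int x = 0; x < nx; ++x) out[base + sx * x] = d[x];
    }

  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  return out;
}
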