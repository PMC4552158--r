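#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian smoothing with mirror (reflect) boundary handling.
// Kernel truncated at 3 sigma. sigma in voxel units; sigma 0 is identity.
// [[Rcpp::export(name = ".gauss3d_cpp")]]
NumericVector gauss3d_cpp(NumericVector vol, IntegerVector dims,
                          double sigma) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out = clone(vol);
  if (sigma <= 0) return out;

  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (int i = 0; i < 2 * r + 1; ++i) k[i] /= s;

  NumericVector tmp(n);
  // reflect index into [0, m-1]
  auto refl = [](int i, int m) {
    if (m == 1) return 0;
    int p = 2 * (m - 1);
    i = ((i % p) + p) % p;
    return i < m ? i : p - i;
  };

  // axis z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int z = 0; z < nz; ++z) {
        double acc = 0;
        for (int i = -r; i <= r; ++i)
          acc += k[i + r] * out[base + refl(z + i, nz)];
        tmp[base + z] = acc;
      }
    }
  // axis y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = z + (R_xlen_t)nz * ny * x;
      for (int y = 0; y < ny; ++y) {
        double acc = 0;
        for (int i = -r; i <= r; ++i)
          acc += k[i + r] * tmp[base + (R_xlen_t)nz * refl(y + i, ny)];
        out[base + (R_xlen_t)nz * y] = acc;
      }
    }
  // axis x
  R_xlen_t sx = (R_xlen_t)nz * ny;
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      R_xlen_t base = z + (R_xlen_t)nz * y;
      for (int x = 0; x < nx; ++x) {
        double acc = 0;
        for (int i = -r; i <= r; ++i)
          acc += k[i + r] * out[base + sx * refl(x + i, nx)];
        tmp[base + sx * x] = acc;
      }
    }
  return tmp;
}
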