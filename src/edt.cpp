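#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Squared Euclidean distance transform of one scan line (Felzenszwalb &
// Huttenlocher lower-envelope-of-parabolas algorithm), with sample step w
// (the voxel spacing along this axis). f holds the running squared
// distances; the result is min_q f(q) + w^2 (p - q)^2.
static void dt1d(const double *f, double *d, int n, double w,
                 std::vector<int> &v, std::vector<double> &z) {
  const double INF = std::numeric_limits<double>::infinity();
  const double w2 = w * w;
  int k = -1;  // index of the rightmost parabola in the envelope
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;  // unreachable sources never contribute
    double s = 0.0;
    while (k >= 0) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k < 0) {  // whole line unreachable
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int k2 = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k2 + 1] < q) ++k2;
    int p = v[k2];
    d[q] = f[p] + w2 * (q - p) * (q - p);
  }
}

// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(IntegerVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> D(n);
  // distance to nearest background voxel centre: background seeds at 0
  for (R_xlen_t i = 0; i < n; ++i) D[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int zi = 0; zi < nz; ++zi)
    for (int yi = 0; yi < ny; ++yi) {
      R_xlen_t base = (R_xlen_t)zi * nx * ny + (R_xlen_t)yi * nx;
      for (int xi = 0; xi < nx; ++xi) f[xi] = D[base + xi];
      dt1d(f.data(), d.data(), nx, spacing[0], v, z);
      for (int xi = 0; xi < nx; ++xi) D[base + xi] = d[xi];
    }
  // pass along y
  for (int zi = 0; zi < nz; ++zi)
    for (int xi = 0; xi < nx; ++xi) {
      R_xlen_t base = (R_xlen_t)zi * nx * ny + xi;
      for (int yi = 0; yi < ny; ++yi) f[yi] = D[base + (R_xlen_t)yi * nx];
      dt1d(f.data(), d.data(), ny, spacing[1], v, z);
      for (int yi = 0; yi < ny; ++yi) D[base + (R_xlen_t)yi * nx] = d[yi];
    }
  // pass along z
  for (int yi = 0; yi < ny; ++yi)
    for (int xi = 0; xi < nx; ++xi) {
      R_xlen_t base = (R_xlen_t)yi * nx + xi;
      for (int zi = 0; zi < nz; ++zi)
        f[zi] = D[base + (R_xlen_t)zi * nx * ny];
      dt1d(f.data(), d.data(), nz, spacing[2], v, z);
      for (int zi = 0; zi < nz; ++zi)
        D[base + (R_xlen_t)zi * nx * ny] = d[zi];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (D[i] == INF) ? NA_REAL : std::sqrt(D[i]);
  return out;
}
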