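// Anisotropic Euclidean distance transform (distance of each foreground voxel
// to the nearest background voxel, in physical units), by the separable
// lower-envelope-of-parabolas algorithm applied per axis with the axis'
// physical sample positions.
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::max() / 4.0;

// 1-D squared distance transform on samples at positions x_i = i * s
void dt1d(const std::vector<double>& f, std::vector<double>& d, int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    while (true) {
      double xv = v[k] * s;
      double sden = 2.0 * (xq - xv);
      double sloc = (f[q] + xq * xq - f[v[k]] - xv * xv) / sden;
      if (sloc <= z[k]) { --k; continue; }
      ++k;
      v[k] = q;
      z[k] = sloc;
      z[k + 1] = INF;
      break;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

} // namespace

// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t N = (size_t)nx * ny * nz;
  std::vector<double> g(N);
  for (size_t i = 0; i < N; ++i) g[i] = mask[i] ? INF : 0.0;

  std::vector<double> f, d;
  // x pass
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      size_t base = (size_t)nx * ((size_t)y + (size_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = g[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }
  // y pass
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = g[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) g[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)] = d[y];
    }
  // z pass
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = g[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) g[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z)] = d[z];
    }

  NumericVector out(N);
  for (size_t i = 0; i < N; ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}
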