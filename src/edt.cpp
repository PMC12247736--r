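// Anisotropic squared Euclidean distance transform, separable lower-envelope
// algorithm (Felzenszwalb & Huttenlocher). Distances are voxel-center to
// voxel-center, in physical units, with independent spacing per axis.
#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform of f sampled at positions x_i = i * s.
void dt1d(const double* f, double* d, int n, double s,
          std::vector<int>& v, std::vector<double>& zbuf) {
  v.resize(n);
  zbuf.resize(n + 1);
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) { // no site on this line; later passes may still resolve it
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  zbuf[0] = -INF;
  zbuf[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double xq = q * s;
    while (true) {
      double xv = v[k] * s;
      double sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (k > 0 && sint <= zbuf[k]) { --k; continue; }
      ++k;
      v[k] = q;
      zbuf[k] = sint;
      zbuf[k + 1] = INF;
      break;
    }
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (zbuf[kk + 1] < xq) ++kk;
    double xv = v[kk] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[kk]];
  }
}

} // namespace

// Squared distance (physical units) from each voxel to the nearest
// background (false) voxel center. Background voxels get 0.
// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::size_t n = static_cast<std::size_t>(nx) * ny * nz;
  std::vector<double> d(n);
  for (std::size_t i = 0; i < n; ++i) d[i] = mask[i] ? INF : 0.0;

  std::vector<int> v;
  std::vector<double> zbuf;
  std::vector<double> line, out;

  // pass along x
  line.resize(nx); out.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      std::size_t base = static_cast<std::size_t>(nx) * (y + static_cast<std::size_t>(ny) * z);
      for (int x = 0; x < nx; ++x) line[x] = d[base + x];
      dt1d(line.data(), out.data(), nx, spacing[0], v, zbuf);
      for (int x = 0; x < nx; ++x) d[base + x] = out[x];
    }
  // pass along y
  line.resize(ny); out.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      std::size_t base = static_cast<std::size_t>(x) + static_cast<std::size_t>(nx) * ny * static_cast<std::size_t>(z);
      for (int y = 0; y < ny; ++y) line[y] = d[base + static_cast<std::size_t>(nx) * y];
      dt1d(line.data(), out.data(), ny, spacing[1], v, zbuf);
      for (int y = 0; y < ny; ++y) d[base + static_cast<std::size_t>(nx) * y] = out[y];
    }
  // pass along z
  line.resize(nz); out.resize(nz);
  std::size_t nxy = static_cast<std::size_t>(nx) * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      std::size_t base = static_cast<std::size_t>(x) + static_cast<std::size_t>(nx) * y;
      for (int z = 0; z < nz; ++z) line[z] = d[base + nxy * z];
      dt1d(line.data(), out.data(), nz, spacing[2], v, zbuf);
      for (int z = 0; z < nz; ++z) d[base + nxy * z] = out[z];
    }

  NumericVector res(n);
  for (std::size_t i = 0; i < n; ++i) res[i] = d[i];
  res.attr("dim") = dims;
  return res;
}
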