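#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher lower-envelope 1D squared distance transform
// on a grid with physical step h (mm). f holds squared distances in, out.
static void dt1d(std::vector<double>& f, double h) {
  const int n = (int)f.size();
  if (n == 0) return;
  const double BIG = 1e29;
  // only finite parabolas enter the lower envelope; mixing the "infinite"
  // placeholder into the intersection formula loses the quadratic term to
  // floating-point cancellation
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  std::vector<double> d(n);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] >= BIG) continue;
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -std::numeric_limits<double>::infinity();
      z[1] = std::numeric_limits<double>::infinity();
      continue;
    }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + q * q * h * h) - (f[p] + p * p * h * h)) / (2.0 * h * h * (q - p));
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    if (s <= z[k] && k == 0) {
      v[0] = q;                       // new parabola dominates everywhere
      z[0] = -std::numeric_limits<double>::infinity();
      z[1] = std::numeric_limits<double>::infinity();
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
      z[k + 1] = std::numeric_limits<double>::infinity();
    }
  }
  if (k < 0) return;                  // no finite source in this line
  // envelope breakpoints are in index units (s = (f_q/h^2 + q^2 - ...)),
  // so queries compare against the index q, not q*h
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < (double)q) ++j;
    double dq = (q - v[j]) * h;
    double cand = dq * dq + f[v[j]];
    if (cand < f[q]) d[q] = cand; else d[q] = f[q];
  }
  f = d;
}

// Euclidean distance (mm) from every voxel to the nearest background voxel
// centre. Voxels outside the volume count as background.
// [[Rcpp::export]]
NumericVector edt3d(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const double INF = 1e30;
  const size_t ntot = (size_t)nx * ny * nz;
  std::vector<double> g(ntot);
  for (size_t i = 0; i < ntot; ++i) g[i] = mask[i] ? INF : 0.0;

  std::vector<double> buf;
  // x pass (fastest-varying index), with implicit background just outside
  buf.resize(nx + 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      size_t base = ((size_t)z * ny + y) * nx;
      buf[0] = 0.0; buf[nx + 1] = 0.0;
      for (int x = 0; x < nx; ++x) buf[x + 1] = g[base + x];
      dt1d(buf, hx);
      for (int x = 0; x < nx; ++x) g[base + x] = buf[x + 1];
    }
  // y pass
  buf.assign(ny + 2, 0.0);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      buf[0] = 0.0; buf[ny + 1] = 0.0;
      for (int y = 0; y < ny; ++y) buf[y + 1] = g[((size_t)z * ny + y) * nx + x];
      dt1d(buf, hy);
      for (int y = 0; y < ny; ++y) g[((size_t)z * ny + y) * nx + x] = buf[y + 1];
    }
  // z pass
  buf.assign(nz + 2, 0.0);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      buf[0] = 0.0; buf[nz + 1] = 0.0;
      for (int z = 0; z < nz; ++z) buf[z + 1] = g[((size_t)z * ny + y) * nx + x];
      dt1d(buf, hz);
      for (int z = 0; z < nz; ++z) g[((size_t)z * ny + y) * nx + x] = buf[z + 1];
    }

  NumericVector out(ntot);
  for (size_t i = 0; i < ntot; ++i) out[i] = std::sqrt(g[i]);
  return out;
}
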