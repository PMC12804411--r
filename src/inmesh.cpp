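#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Parity (even-odd) point-in-mesh test for a whole voxel grid against a
// closed triangle mesh. One ray is cast along +x per (y, z) grid line; the
// x-coordinates of triangle crossings split the line into inside/outside
// intervals shared by all voxels on that line. Ray origins carry a tiny
// fixed offset so that edge/vertex grazing hits have measure zero.
// [[Rcpp::export]]
LogicalVector voxel_inside_mesh(NumericMatrix V, IntegerMatrix F,
                                NumericVector origin, double spacing,
                                IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nf = F.nrow();
  // distinct, incommensurate offsets per axis so rays cannot lie exactly on
  // a projected mesh edge (including diagonal fan edges)
  const double epsy = spacing * 1.37e-4 + 1e-9;
  const double epsz = spacing * 0.61e-4 + 2e-9;

  std::vector<double> y1(nf), z1(nf), y2(nf), z2(nf), y3(nf), z3(nf), x1(nf), x2(nf), x3(nf);
  std::vector<double> ymin(nf), ymax(nf), zmin(nf), zmax(nf);
  for (int t = 0; t < nf; ++t) {
    int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
    x1[t] = V(a, 0); y1[t] = V(a, 1); z1[t] = V(a, 2);
    x2[t] = V(b, 0); y2[t] = V(b, 1); z2[t] = V(b, 2);
    x3[t] = V(c, 0); y3[t] = V(c, 1); z3[t] = V(c, 2);
    ymin[t] = std::min({y1[t], y2[t], y3[t]});
    ymax[t] = std::max({y1[t], y2[t], y3[t]});
    zmin[t] = std::min({z1[t], z2[t], z3[t]});
    zmax[t] = std::max({z1[t], z2[t], z3[t]});
  }

  LogicalVector out((size_t)nx * ny * nz);
  std::vector<double> xs;
  for (int iz = 0; iz < nz; ++iz) {
    double zr = origin[2] + iz * spacing + epsz;
    for (int iy = 0; iy < ny; ++iy) {
      double yr = origin[1] + iy * spacing + epsy;
      xs.clear();
      for (int t = 0; t < nf; ++t) {
        if (yr < ymin[t] || yr > ymax[t] || zr < zmin[t] || zr > zmax[t]) continue;
        // barycentric coordinates in the (y, z) projection
        double d = (y2[t] - y1[t]) * (z3[t] - z1[t]) - (y3[t] - y1[t]) * (z2[t] - z1[t]);
        if (std::fabs(d) < 1e-14) continue; // triangle parallel to the ray
        double l2 = ((yr - y1[t]) * (z3[t] - z1[t]) - (y3[t] - y1[t]) * (zr - z1[t])) / d;
        double l3 = ((y2[t] - y1[t]) * (zr - z1[t]) - (yr - y1[t]) * (z2[t] - z1[t])) / d;
        double l1 = 1.0 - l2 - l3;
        if (l1 < 0 || l2 < 0 || l3 < 0) continue;
        xs.push_back(l1 * x1[t] + l2 * x2[t] + l3 * x3[t]);
      }
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      size_t base = ((size_t)iz * ny + iy) * nx;
      for (int ix = 0; ix < nx; ++ix) {
        double xv = origin[0] + ix * spacing;
        size_t cnt = std::upper_bound(xs.begin(), xs.end(), xv) - xs.begin();
        out[base + ix] = (cnt % 2) == 1;
      }
    }
  }
  return out;
}
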