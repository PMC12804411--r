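#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact nearest neighbour from each query row to the target set, using a
// uniform grid locator with expanding-shell search.
// [[Rcpp::export]]
List nn_grid(NumericMatrix query, NumericMatrix target, double cell = -1.0) {
  const int nq = query.nrow(), nt = target.nrow();
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = std::numeric_limits<double>::infinity();
    hi[d] = -std::numeric_limits<double>::infinity();
  }
  for (int i = 0; i < nt; ++i)
    for (int d = 0; d < 3; ++d) {
      if (target(i, d) < lo[d]) lo[d] = target(i, d);
      if (target(i, d) > hi[d]) hi[d] = target(i, d);
    }
  double vol = 1.0;
  for (int d = 0; d < 3; ++d) vol *= std::max(hi[d] - lo[d], 1e-9);
  if (cell <= 0) cell = std::max(std::cbrt(vol / std::max(nt, 1)) * 2.0, 1e-6);
  int dims[3];
  for (int d = 0; d < 3; ++d)
    dims[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cell) + 1);
  const size_t ncell = (size_t)dims[0] * dims[1] * dims[2];

  std::vector<std::vector<int> > bins(ncell);
  auto cell_of = [&](double x, double y, double z, int* c) {
    c[0] = std::min(dims[0] - 1, std::max(0, (int)std::floor((x - lo[0]) / cell)));
    c[1] = std::min(dims[1] - 1, std::max(0, (int)std::floor((y - lo[1]) / cell)));
    c[2] = std::min(dims[2] - 1, std::max(0, (int)std::floor((z - lo[2]) / cell)));
  };
  for (int i = 0; i < nt; ++i) {
    int c[3];
    cell_of(target(i, 0), target(i, 1), target(i, 2), c);
    bins[((size_t)c[2] * dims[1] + c[1]) * dims[0] + c[0]].push_back(i);
  }

  IntegerVector idx(nq);
  NumericVector d2(nq);
  const int max_ring = dims[0] + dims[1] + dims[2];
  for (int q = 0; q < nq; ++q) {
    double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    int c[3];
    cell_of(qx, qy, qz, c);
    double best = std::numeric_limits<double>::infinity();
    int best_i = -1;
    for (int ring = 0; ring <= max_ring; ++ring) {
      // once a candidate is known, stop when the closest possible point in
      // this ring is farther than the current best
      if (best_i >= 0) {
        double min_ring_dist = (ring - 1) * cell;
        if (min_ring_dist > 0 && min_ring_dist * min_ring_dist > best) break;
      }
      bool any_cell = false;
      for (int dz = -ring; dz <= ring; ++dz) {
        int z = c[2] + dz;
        if (z < 0 || z >= dims[2]) continue;
        for (int dy = -ring; dy <= ring; ++dy) {
          int y = c[1] + dy;
          if (y < 0 || y >= dims[1]) continue;
          for (int dx = -ring; dx <= ring; ++dx) {
            // shell only: at least one offset at the ring boundary
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != ring)
              continue;
            int x = c[0] + dx;
            if (x < 0 || x >= dims[0]) continue;
            any_cell = true;
            const std::vector<int>& b =
              bins[((size_t)z * dims[1] + y) * dims[0] + x];
            for (size_t k = 0; k < b.size(); ++k) {
              int i = b[k];
              double ddx = target(i, 0) - qx;
              double ddy = target(i, 1) - qy;
              double ddz = target(i, 2) - qz;
              double dd = ddx * ddx + ddy * ddy + ddz * ddz;
              if (dd < best) { best = dd; best_i = i; }
            }
          }
        }
      }
      if (!any_cell && best_i >= 0) break;
    }
    idx[q] = best_i + 1;
    d2[q] = best;
  }
  return List::create(_["index"] = idx, _["d2"] = d2);
}
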