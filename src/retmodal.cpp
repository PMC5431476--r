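#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Bilateral filter on a 2D image (values on the 0-255 scale).
// Spatial kernel: Gaussian with sd sigma_s (voxels), truncated at `radius`.
// Range kernel: Gaussian with sd sigma_r (gray levels). Out-of-bounds
// neighbours are skipped (weights renormalized), so border pixels average
// over their in-bounds neighbourhood; output stays within the input range.
// [[Rcpp::export]]
NumericMatrix cpp_bilateral(NumericMatrix img, double sigma_s, double sigma_r,
                            int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  const double inv2ss = 1.0 / (2.0 * sigma_s * sigma_s);
  const double inv2sr = 1.0 / (2.0 * sigma_r * sigma_r);
  // precompute spatial weights
  const int w = 2 * radius + 1;
  std::vector<double> sw(w * w);
  for (int di = -radius; di <= radius; ++di)
    for (int dj = -radius; dj <= radius; ++dj)
      sw[(di + radius) * w + (dj + radius)] =
          std::exp(-(double)(di * di + dj * dj) * inv2ss);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double c = img(i, j);
      double acc = 0.0, wacc = 0.0;
      for (int di = -radius; di <= radius; ++di) {
        const int ii = i + di;
        if (ii < 0 || ii >= nr) continue;
        for (int dj = -radius; dj <= radius; ++dj) {
          const int jj = j + dj;
          if (jj < 0 || jj >= nc) continue;
          const double v = img(ii, jj);
          const double d = v - c;
          const double wt = sw[(di + radius) * w + (dj + radius)] *
                            std::exp(-d * d * inv2sr);
          acc += wt * v;
          wacc += wt;
        }
      }
      out(i, j) = acc / wacc;
    }
  }
  return out;
}

// Minimum-cost left-to-right path by dynamic programming.
// cost: nrow = sequence positions (A-scans), ncol = states (axial indices
// within the search band). Consecutive states may differ by at most
// max_jump. Ties broken toward the smallest state index. Returns the
// 1-based state per position and the total path cost.
// [[Rcpp::export]]
List cpp_dp_boundary(NumericMatrix cost, int max_jump) {
  const int n = cost.nrow(), m = cost.ncol();
  NumericMatrix D(n, m);
  IntegerMatrix back(n, m);
  for (int z = 0; z < m; ++z) D(0, z) = cost(0, z);
  for (int i = 1; i < n; ++i) {
    for (int z = 0; z < m; ++z) {
      double best = R_PosInf;
      int arg = -1;
      const int lo = std::max(0, z - max_jump);
      const int hi = std::min(m - 1, z + max_jump);
      for (int p = lo; p <= hi; ++p) {
        if (D(i - 1, p) < best) { best = D(i - 1, p); arg = p; }
      }
      D(i, z) = cost(i, z) + best;
      back(i, z) = arg;
    }
  }
  double best = R_PosInf;
  int arg = 0;
  for (int z = 0; z < m; ++z)
    if (D(n - 1, z) < best) { best = D(n - 1, z); arg = z; }
  IntegerVector path(n);
  path[n - 1] = arg + 1;
  for (int i = n - 1; i > 0; --i) {
    arg = back(i, arg);
    path[i - 1] = arg + 1;
  }
  return List::create(_["path"] = path, _["cost"] = best);
}

// Seeded region growing on a 2D image. Seeds are first grouped into
// 8-connected components; each component grows by BFS over 8-neighbours,
// admitting a pixel iff it lies in `band` and its intensity is at least
// (mean intensity of the seed component) - delta. The union of all grown
// components is returned.
// [[Rcpp::export]]
LogicalMatrix cpp_region_grow(NumericMatrix img, LogicalMatrix seeds,
                              LogicalMatrix band, double delta) {
  const int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix out(nr, nc);
  IntegerMatrix comp(nr, nc);   // seed-component id, 0 = none
  IntegerMatrix vis(nr, nc);    // last component that visited (growth phase)
  std::vector<double> cmean;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int ncomp = 0;
  // label seed components and their means
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!seeds(i, j) || comp(i, j) != 0) continue;
      ++ncomp;
      double s = 0.0; int cnt = 0;
      std::queue<std::pair<int, int> > q;
      comp(i, j) = ncomp;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        s += img(p.first, p.second); ++cnt;
        for (int k = 0; k < 8; ++k) {
          const int ii = p.first + dr[k], jj = p.second + dc[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (seeds(ii, jj) && comp(ii, jj) == 0) {
            comp(ii, jj) = ncomp;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
      cmean.push_back(s / cnt);
    }
  }
  // grow each component with its own admission threshold
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const int id = comp(i, j);
      if (id == 0 || vis(i, j) == id) continue;
      const double thr = cmean[id - 1] - delta;
      std::queue<std::pair<int, int> > q;
      vis(i, j) = id;
      out(i, j) = true;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int k = 0; k < 8; ++k) {
          const int ii = p.first + dr[k], jj = p.second + dc[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (vis(ii, jj) == id) continue;
          if (!band(ii, jj) || img(ii, jj) < thr) continue;
          vis(ii, jj) = id;
          out(ii, jj) = true;
          q.push(std::make_pair(ii, jj));
        }
      }
    }
  }
  return out;
}

// 26-connectivity component labeling of a 3D logical mask.
// mask is a logical vector in column-major order with dims (nx, ny, nz).
// Returns an integer vector of the same length: 0 background, 1..K labels
// in first-encounter (column-major scan) order.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back(); stack.pop_back();
      const int x = cur % nx;
      const int y = (cur / nx) % ny;
      const int z = cur / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz) {
        const int zz = z + dz;
        if (zz < 0 || zz >= nz) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= ny) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            const int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const R_xlen_t nb = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (mask[nb] && lab[nb] == 0) {
              lab[nb] = next;
              stack.push_back(nb);
            }
          }
        }
      }
    }
  }
  return lab;
}
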