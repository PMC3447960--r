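#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Simple 3-D cell list over a cubic grid. Cells are addressed by linear
// index; particles are chained through head/next arrays.
struct CellList {
  double cell, x0, y0, z0;
  int nx, ny, nz;
  std::vector<int> head, nxt, cell_of;

  CellList(const std::vector<double>& x, const std::vector<double>& y,
           const std::vector<double>& z, double cell_size) {
    cell = cell_size;
    double xmin = *std::min_element(x.begin(), x.end());
    double ymin = *std::min_element(y.begin(), y.end());
    double zmin = *std::min_element(z.begin(), z.end());
    double xmax = *std::max_element(x.begin(), x.end());
    double ymax = *std::max_element(y.begin(), y.end());
    double zmax = *std::max_element(z.begin(), z.end());
    // grow the cell size if the grid would be huge (ring searches stay
    // correct for any cell >= the query cutoff)
    for (;;) {
      double cx = std::ceil((xmax - xmin) / cell) + 5;
      double cy = std::ceil((ymax - ymin) / cell) + 5;
      double cz = std::ceil((zmax - zmin) / cell) + 5;
      if (cx * cy * cz <= 1.6e7) break;
      cell *= 2;
    }
    // pad by one cell so moved particles stay in range
    x0 = xmin - 2 * cell; y0 = ymin - 2 * cell; z0 = zmin - 2 * cell;
    nx = (int)std::ceil((xmax - x0) / cell) + 3;
    ny = (int)std::ceil((ymax - y0) / cell) + 3;
    nz = (int)std::ceil((zmax - z0) / cell) + 3;
    head.assign((size_t)nx * ny * nz, -1);
    int n = x.size();
    nxt.assign(n, -1);
    cell_of.assign(n, -1);
    for (int i = 0; i < n; ++i) insert(i, x[i], y[i], z[i]);
  }

  int cell_index(double px, double py, double pz) const {
    int ix = (int)((px - x0) / cell);
    int iy = (int)((py - y0) / cell);
    int iz = (int)((pz - z0) / cell);
    if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
    if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
    if (iz < 0) iz = 0; if (iz >= nz) iz = nz - 1;
    return (ix * ny + iy) * nz + iz;
  }

  void insert(int i, double px, double py, double pz) {
    int c = cell_index(px, py, pz);
    nxt[i] = head[c];
    head[c] = i;
    cell_of[i] = c;
  }

  void remove(int i) {
    int c = cell_of[i];
    int j = head[c];
    if (j == i) { head[c] = nxt[i]; return; }
    while (j >= 0 && nxt[j] != i) j = nxt[j];
    if (j >= 0) nxt[j] = nxt[i];
  }

  void move(int i, double px, double py, double pz) {
    int c = cell_index(px, py, pz);
    if (c == cell_of[i]) return;
    remove(i);
    nxt[i] = head[c];
    head[c] = i;
    cell_of[i] = c;
  }

  template <class F>
  void for_neighbours(double px, double py, double pz, int ring, F f) const {
    int ix = (int)((px - x0) / cell);
    int iy = (int)((py - y0) / cell);
    int iz = (int)((pz - z0) / cell);
    for (int dx = -ring; dx <= ring; ++dx) {
      int cx = ix + dx; if (cx < 0 || cx >= nx) continue;
      for (int dy = -ring; dy <= ring; ++dy) {
        int cy = iy + dy; if (cy < 0 || cy >= ny) continue;
        for (int dz = -ring; dz <= ring; ++dz) {
          int cz = iz + dz; if (cz < 0 || cz >= nz) continue;
          for (int j = head[(cx * (size_t)ny + cy) * nz + cz]; j >= 0; j = nxt[j]) {
            f(j);
          }
        }
      }
    }
  }
};

static std::vector<double> col_to_vec(const NumericMatrix& m, int j) {
  std::vector<double> v(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) v[i] = m(i, j);
  return v;
}

// All pairs (i < j, 1-based) closer than cutoff.
// [[Rcpp::export]]
IntegerMatrix close_pairs_cpp(NumericMatrix coords, double cutoff) {
  int n = coords.nrow();
  std::vector<double> x = col_to_vec(coords, 0), y = col_to_vec(coords, 1),
    z = col_to_vec(coords, 2);
  CellList cl(x, y, z, cutoff);
  std::vector<int> ai, aj;
  double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    cl.for_neighbours(x[i], y[i], z[i], 1, [&](int j) {
      if (j <= i) return;
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      if (dx * dx + dy * dy + dz * dz < c2) { ai.push_back(i + 1); aj.push_back(j + 1); }
    });
  }
  IntegerMatrix out(ai.size(), 2);
  for (size_t k = 0; k < ai.size(); ++k) { out(k, 0) = ai[k]; out(k, 1) = aj[k]; }
  return out;
}

// k nearest neighbours within the same group (1-based indices, n x k).
// [[Rcpp::export]]
IntegerMatrix knn_same_group_cpp(NumericMatrix coords, IntegerVector group,
                                 int k, double cell_size) {
  int n = coords.nrow();
  if (k >= n) stop("k must be smaller than the number of points");
  std::vector<double> x = col_to_vec(coords, 0), y = col_to_vec(coords, 1),
    z = col_to_vec(coords, 2);
  CellList cl(x, y, z, cell_size);
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int> > cand;
  int max_ring = std::max(cl.nx, std::max(cl.ny, cl.nz));
  for (int i = 0; i < n; ++i) {
    for (int ring = 1; ring <= max_ring; ++ring) {
      cand.clear();
      cl.for_neighbours(x[i], y[i], z[i], ring, [&](int j) {
        if (j == i || group[j] != group[i]) return;
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        cand.push_back(std::make_pair(dx * dx + dy * dy + dz * dz, j));
      });
      if ((int)cand.size() >= k) {
        std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
        // complete only if the kth distance fits inside the searched shell
        // (a point at distance d can sit one cell beyond d/cell rings)
        double guaranteed = (ring - 1) * cl.cell;
        if (std::sqrt(cand[k - 1].first) <= guaranteed || ring == max_ring) {
          for (int m = 0; m < k; ++m) out(i, m) = cand[m].second + 1;
          break;
        }
      } else if (ring == max_ring) {
        stop("not enough same-group neighbours");
      }
    }
  }
  return out;
}

// Metropolis Monte Carlo of lipid headgroups on their leaflet spheres.
// Energy: -eps[i] when within `range` of any site, else 0 (kT = 1).
// Proposals are Gaussian tangent-plane steps re-projected to the sphere;
// moves bringing two same-leaflet lipids closer than min_sep are rejected
// (hard core). One sweep = one attempted move per lipid. Uses R's RNG.
// [[Rcpp::export]]
List mc_lipid_dynamics_cpp(NumericMatrix coords, NumericVector radius,
                           IntegerVector leaflet, NumericVector eps,
                           NumericMatrix sites, double range, double step,
                           int n_sweeps, int stride, double min_sep) {
  if (step <= 0) stop("step length must be positive");
  int n = coords.nrow(), ns = sites.nrow();
  std::vector<double> x = col_to_vec(coords, 0), y = col_to_vec(coords, 1),
    z = col_to_vec(coords, 2);
  double cell_size = std::max(min_sep, 1e-6);
  CellList cl(x, y, z, cell_size);
  double r2 = range * range, ms2 = min_sep * min_sep;

  auto in_shell = [&](double px, double py, double pz) -> bool {
    for (int s = 0; s < ns; ++s) {
      double dx = px - sites(s, 0), dy = py - sites(s, 1), dz = pz - sites(s, 2);
      if (dx * dx + dy * dy + dz * dz <= r2) return true;
    }
    return false;
  };

  std::vector<NumericMatrix> frames;
  std::vector<int> frame_sweeps;
  auto record = [&](int sweep) {
    NumericMatrix f(n, 3);
    for (int i = 0; i < n; ++i) { f(i, 0) = x[i]; f(i, 1) = y[i]; f(i, 2) = z[i]; }
    frames.push_back(f);
    frame_sweeps.push_back(sweep);
  };

  GetRNGstate();
  record(0);
  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int i = 0; i < n; ++i) {
      double nxv = x[i] / radius[i], nyv = y[i] / radius[i], nzv = z[i] / radius[i];
      // tangent basis
      double rx = (std::fabs(nxv) < 0.9) ? 1.0 : 0.0, ry = 1.0 - rx, rz = 0.0;
      double e1x = ry * nzv - rz * nyv, e1y = rz * nxv - rx * nzv,
        e1z = rx * nyv - ry * nxv;
      double e1n = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
      e1x /= e1n; e1y /= e1n; e1z /= e1n;
      double e2x = nyv * e1z - nzv * e1y, e2y = nzv * e1x - nxv * e1z,
        e2z = nxv * e1y - nyv * e1x;
      double a = step * norm_rand(), b = step * norm_rand();
      double px = x[i] + a * e1x + b * e2x;
      double py = y[i] + a * e1y + b * e2y;
      double pz = z[i] + a * e1z + b * e2z;
      double pn = radius[i] / std::sqrt(px * px + py * py + pz * pz);
      px *= pn; py *= pn; pz *= pn;
      // hard core against same-leaflet neighbours
      bool clash = false;
      cl.for_neighbours(px, py, pz, 1, [&](int j) {
        if (clash || j == i || leaflet[j] != leaflet[i]) return;
        double dx = px - x[j], dy = py - y[j], dz = pz - z[j];
        if (dx * dx + dy * dy + dz * dz < ms2) clash = true;
      });
      if (clash) continue;
      double e_old = in_shell(x[i], y[i], z[i]) ? -eps[i] : 0.0;
      double e_new = in_shell(px, py, pz) ? -eps[i] : 0.0;
      double dE = e_new - e_old;
      if (dE > 0 && unif_rand() >= std::exp(-dE)) continue;
      x[i] = px; y[i] = py; z[i] = pz;
      cl.move(i, px, py, pz);
    }
    if (sweep % stride == 0) record(sweep);
  }
  PutRNGstate();

  List lf(frames.size());
  for (size_t i = 0; i < frames.size(); ++i) lf[i] = frames[i];
  return List::create(_["frames"] = lf,
                      _["sweeps"] = IntegerVector(frame_sweeps.begin(),
                                                  frame_sweeps.end()));
}
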