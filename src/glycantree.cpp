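// Pairwise-energy and density kernels.  These are the only hot loops in the
// Monte Carlo sampler; everything else stays in R.
#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline double dist2(const NumericMatrix& xyz, int i, int j) {
  double dx = xyz(i, 0) - xyz(j, 0);
  double dy = xyz(i, 1) - xyz(j, 1);
  double dz = xyz(i, 2) - xyz(j, 2);
  return dx * dx + dy * dy + dz * dz;
}

// covalent bonds by element-aware distance criterion; returns 1-based pairs
// [[Rcpp::export]]
IntegerMatrix cpp_detect_bonds(NumericMatrix xyz, LogicalVector is_h,
                               double heavy_cut, double h_cut) {
  int n = xyz.nrow();
  std::vector<int> ai, aj;
  double hc2 = heavy_cut * heavy_cut, xc2 = h_cut * h_cut;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (is_h[i] && is_h[j]) continue;
      double cut2 = (is_h[i] || is_h[j]) ? xc2 : hc2;
      double d2 = dist2(xyz, i, j);
      if (d2 < cut2 && d2 > 0.25) {  // > 0.5 A guards against duplicates
        ai.push_back(i + 1);
        aj.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out(ai.size(), 2);
  for (size_t k = 0; k < ai.size(); ++k) { out(k, 0) = ai[k]; out(k, 1) = aj[k]; }
  return out;
}

// all pairs within `max_sep` bonds of each other (1-2, 1-3, 1-4 for
// max_sep = 3); input/output 1-based
// [[Rcpp::export]]
IntegerMatrix cpp_bond_exclusions(IntegerMatrix bonds, int n, int max_sep) {
  std::vector<std::vector<int>> adj(n);
  for (int k = 0; k < bonds.nrow(); ++k) {
    int a = bonds(k, 0) - 1, b = bonds(k, 1) - 1;
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  std::vector<int> pi, pj;
  std::vector<int> depth(n);
  for (int s = 0; s < n; ++s) {
    std::fill(depth.begin(), depth.end(), -1);
    std::queue<int> q;
    q.push(s); depth[s] = 0;
    while (!q.empty()) {
      int u = q.front(); q.pop();
      if (depth[u] == max_sep) continue;
      for (int v : adj[u]) {
        if (depth[v] < 0) {
          depth[v] = depth[u] + 1;
          if (v > s) { pi.push_back(s + 1); pj.push_back(v + 1); }
          q.push(v);
        }
      }
    }
  }
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) { out(k, 0) = pi[k]; out(k, 1) = pj[k]; }
  return out;
}

// Soft sterics: for heavy-atom pairs with one member in `sel` and the other
// in `partner`, excluding bonded (1-2/1-3/1-4) pairs:
//   r <  r0        : min(cap, (r0/r)^12 - 1)            (repulsive)
//   r0 <= r <= rmax: -eps * (r0/r)^6 * switch(r)         (attractive well)
// with switch = 1 below rs and a cosine taper on [rs, rmax].
// sel/partner are 1-based atom rows; radii is the per-atom element radius.
// [[Rcpp::export]]
List cpp_steric_energy(NumericMatrix xyz, IntegerVector sel,
                       IntegerVector partner, NumericVector radii,
                       LogicalVector is_h, NumericVector excl_keys,
                       double eps, double cap, double rs, double rmax) {
  // excl_keys: sorted encoded pairs (i-1)*n + (j-1), both orders
  int n = xyz.nrow();
  const double* ek = excl_keys.begin();
  int nek = excl_keys.size();
  std::vector<char> in_sel(n, 0);
  for (int k = 0; k < sel.size(); ++k) in_sel[sel[k] - 1] = 1;
  double rep = 0.0, atr = 0.0;
  double rmax2 = rmax * rmax;
  for (int a = 0; a < sel.size(); ++a) {
    int i = sel[a] - 1;
    if (is_h[i]) continue;
    for (int b = 0; b < partner.size(); ++b) {
      int j = partner[b] - 1;
      if (is_h[j] || i == j) continue;
      if (in_sel[j] && j <= i) continue;  // count sel-sel pairs once
      double d2 = dist2(xyz, i, j);
      if (d2 > rmax2) continue;
      double key = (double)i * n + j;
      if (nek && std::binary_search(ek, ek + nek, key)) continue;
      double r0 = radii[i] + radii[j];
      double r = std::sqrt(d2);
      if (r < r0) {
        double q = r0 / std::max(r, 1e-6);
        double q3 = q * q * q;
        double e = q3 * q3 * q3 * q3 - 1.0;  // (r0/r)^12 - 1
        rep += (e > cap) ? cap : e;
      } else {
        double q = r0 / r;
        double q6 = q * q * q * q * q * q;
        double sw = 1.0;
        if (r > rs) sw = 0.5 * (1.0 + std::cos(M_PI * (r - rs) / (rmax - rs)));
        atr += -eps * q6 * sw;
      }
    }
  }
  return List::create(Named("rep") = rep, Named("atr") = atr);
}

// Geometric hydrogen bonds: donor hydrogen H (bonded to heavy donor D) and
// acceptor A score  -1 * wd(|D-A|) * wa(angle D-H-A)  with a cosine-smoothed
// distance window on [2.6, 3.4] peaking at 2.9 and an angle window opening
// at 120 deg and peaking at 180 deg.  A pair is scored when at least one of
// its atoms is in the moving selection and both are allowed (unmasked).
// [[Rcpp::export]]
double cpp_hbond_energy(NumericMatrix xyz, IntegerVector don_h,
                        IntegerVector don_d, IntegerVector acc,
                        LogicalVector in_sel, LogicalVector allowed) {
  double e = 0.0;
  for (int a = 0; a < don_h.size(); ++a) {
    int h = don_h[a] - 1, d = don_d[a] - 1;
    if (!allowed[h] || !allowed[d]) continue;
    for (int b = 0; b < acc.size(); ++b) {
      int ac = acc[b] - 1;
      if (ac == d) continue;
      if (!allowed[ac]) continue;
      if (!(in_sel[h] || in_sel[d] || in_sel[ac])) continue;
      double r2 = dist2(xyz, d, ac);
      if (r2 < 2.6 * 2.6 || r2 > 3.4 * 3.4) continue;
      double r = std::sqrt(r2);
      double wd;
      if (r <= 2.9) wd = 0.5 * (1.0 - std::cos(M_PI * (r - 2.6) / 0.3));
      else          wd = 0.5 * (1.0 + std::cos(M_PI * (r - 2.9) / 0.5));
      // angle D-H...A at the hydrogen
      double ux = xyz(d, 0) - xyz(h, 0), uy = xyz(d, 1) - xyz(h, 1), uz = xyz(d, 2) - xyz(h, 2);
      double vx = xyz(ac, 0) - xyz(h, 0), vy = xyz(ac, 1) - xyz(h, 1), vz = xyz(ac, 2) - xyz(h, 2);
      double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
      double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
      if (nu < 1e-9 || nv < 1e-9) continue;
      double ct = (ux * vx + uy * vy + uz * vz) / (nu * nv);
      ct = std::max(-1.0, std::min(1.0, ct));
      double theta = std::acos(ct) * 180.0 / M_PI;
      if (theta <= 120.0) continue;
      double wa = 0.5 * (1.0 - std::cos(M_PI * (theta - 120.0) / 60.0));
      e += -1.0 * wd * wa;
    }
  }
  return e;
}

// Sum of isotropic atom Gaussians accumulated on a grid (column-major,
// x fastest).  Contributions are truncated at trunc_mult * sigma.
// [[Rcpp::export]]
NumericVector cpp_sum_gaussians(NumericMatrix coords, NumericVector origin,
                                IntegerVector dims, double voxel,
                                double sigma, double trunc_mult) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector grid(nx * ny * nz);
  double rad = trunc_mult * sigma;
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int a = 0; a < coords.nrow(); ++a) {
    double x = coords(a, 0), y = coords(a, 1), z = coords(a, 2);
    int ix0 = std::max(0, (int)std::floor((x - rad - origin[0]) / voxel));
    int ix1 = std::min(nx - 1, (int)std::ceil((x + rad - origin[0]) / voxel));
    int iy0 = std::max(0, (int)std::floor((y - rad - origin[1]) / voxel));
    int iy1 = std::min(ny - 1, (int)std::ceil((y + rad - origin[1]) / voxel));
    int iz0 = std::max(0, (int)std::floor((z - rad - origin[2]) / voxel));
    int iz1 = std::min(nz - 1, (int)std::ceil((z + rad - origin[2]) / voxel));
    for (int iz = iz0; iz <= iz1; ++iz) {
      double dz = origin[2] + iz * voxel - z;
      for (int iy = iy0; iy <= iy1; ++iy) {
        double dy = origin[1] + iy * voxel - y;
        for (int ix = ix0; ix <= ix1; ++ix) {
          double dx = origin[0] + ix * voxel - x;
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 > rad * rad) continue;
          grid[ix + nx * (iy + (long long)ny * iz)] += std::exp(-d2 * inv2s2);
        }
      }
    }
  }
  return grid;
}

// Voxel indices (1-based, column-major) within `radius` of any atom.
// [[Rcpp::export]]
IntegerVector cpp_mask_indices(NumericMatrix coords, NumericVector origin,
                               IntegerVector dims, double voxel, double radius) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<char> mask((size_t)nx * ny * nz, 0);
  double r2 = radius * radius;
  for (int a = 0; a < coords.nrow(); ++a) {
    double x = coords(a, 0), y = coords(a, 1), z = coords(a, 2);
    int ix0 = std::max(0, (int)std::floor((x - radius - origin[0]) / voxel));
    int ix1 = std::min(nx - 1, (int)std::ceil((x + radius - origin[0]) / voxel));
    int iy0 = std::max(0, (int)std::floor((y - radius - origin[1]) / voxel));
    int iy1 = std::min(ny - 1, (int)std::ceil((y + radius - origin[1]) / voxel));
    int iz0 = std::max(0, (int)std::floor((z - radius - origin[2]) / voxel));
    int iz1 = std::min(nz - 1, (int)std::ceil((z + radius - origin[2]) / voxel));
    for (int iz = iz0; iz <= iz1; ++iz) {
      double dz = origin[2] + iz * voxel - z;
      for (int iy = iy0; iy <= iy1; ++iy) {
        double dy = origin[1] + iy * voxel - y;
        for (int ix = ix0; ix <= ix1; ++ix) {
          double dx = origin[0] + ix * voxel - x;
          if (dx * dx + dy * dy + dz * dz <= r2)
            mask[ix + nx * (iy + (size_t)ny * iz)] = 1;
        }
      }
    }
  }
  std::vector<int> idx;
  for (size_t k = 0; k < mask.size(); ++k)
    if (mask[k]) idx.push_back((int)k + 1);
  return wrap(idx);
}
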