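// Shared geometry utilities for periodic hard-sphere systems.
#pragma once
#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <cmath>

typedef arma::vec::fixed<3> vec3;

// Orthorhombic periodic box (cubic is the common case).
struct PBox {
  double L[3];
  PBox(const Rcpp::NumericVector& Lv) {
    if (Lv.size() == 1) { L[0] = L[1] = L[2] = Lv[0]; }
    else { L[0] = Lv[0]; L[1] = Lv[1]; L[2] = Lv[2]; }
  }
  inline double wrap1(double x, int k) const {
    x -= L[k] * std::floor(x / L[k]);
    if (x >= L[k]) x -= L[k];
    if (x < 0) x += L[k];
    return x;
  }
  inline vec3 wrap(const vec3& p) const {
    vec3 q;
    for (int k = 0; k < 3; ++k) q[k] = wrap1(p[k], k);
    return q;
  }
  // displacement q - p folded to the nearest image, components in (-L/2, L/2]
  inline vec3 minimg(const vec3& d) const {
    vec3 r;
    for (int k = 0; k < 3; ++k) {
      double x = d[k] - L[k] * std::round(d[k] / L[k]);
      if (x <= -0.5 * L[k]) x += L[k];
      r[k] = x;
    }
    return r;
  }
  inline double dist2(const vec3& p, const vec3& q) const {
    vec3 d = minimg(q - p);
    return arma::dot(d, d);
  }
  // fast path for coordinates already wrapped into [0, L): |dx| <= L, and
  // folding by one box length gives the minimum image without divisions
  inline double dist2w(const vec3& p, const vec3& q) const {
    double s = 0.0;
    for (int k = 0; k < 3; ++k) {
      double d = p[k] - q[k];
      if (d < 0) d = -d;
      if (d > 0.5 * L[k]) d = L[k] - d;
      s += d * d;
    }
    return s;
  }
  inline double volume() const { return L[0] * L[1] * L[2]; }
};

// Linked-cell list for O(1) local overlap queries; falls back to brute force
// when the box holds fewer than 3 cells along any axis.
struct CellList {
  const PBox* box;
  int nc[3];
  bool brute;
  std::vector<std::vector<int>> cells;
  std::vector<int> where;   // site -> cell index, -1 if absent
  std::vector<int> nbr27;   // per-cell list of the 27 neighbour cells

  // re-initialize keeping allocated capacity where the grid is unchanged
  void init(const PBox& b, int n_sites, double min_edge) {
    box = &b;
    // keep mean occupancy O(1): oversized sparse grids thrash the cache
    int cap = std::max(3, (int)std::cbrt(4.0 * std::max(1, n_sites)));
    for (int k = 0; k < 3; ++k)
      nc[k] = std::min(cap, std::max(1, (int)std::floor(b.L[k] / min_edge)));
    brute = (nc[0] < 3 || nc[1] < 3 || nc[2] < 3);
    if (brute) { nc[0] = nc[1] = nc[2] = 1; }
    size_t ncell = (size_t)nc[0] * nc[1] * nc[2];
    bool same_grid = (cells.size() == ncell && !nbr27.empty() == !brute);
    if (same_grid) {
      for (auto& c : cells) c.clear();
    } else {
      cells.assign(ncell, {});
      nbr27.clear();
      if (!brute) {
        nbr27.resize(ncell * 27);
        size_t t = 0;
        for (int cz = 0; cz < nc[2]; ++cz)
          for (int cy = 0; cy < nc[1]; ++cy)
            for (int cx = 0; cx < nc[0]; ++cx)
              for (int dz = -1; dz <= 1; ++dz)
                for (int dy = -1; dy <= 1; ++dy)
                  for (int dx = -1; dx <= 1; ++dx) {
                    int x = (cx + dx + nc[0]) % nc[0];
                    int y = (cy + dy + nc[1]) % nc[1];
                    int z = (cz + dz + nc[2]) % nc[2];
                    nbr27[t++] = (z * nc[1] + y) * nc[0] + x;
                  }
      }
    }
    where.assign(n_sites, -1);
  }
  inline int cidx(const vec3& p) const {
    int ix[3];
    for (int k = 0; k < 3; ++k) {
      int i = (int)std::floor(p[k] / box->L[k] * nc[k]);
      if (i < 0) i = 0;
      if (i >= nc[k]) i = nc[k] - 1;
      ix[k] = i;
    }
    return (ix[2] * nc[1] + ix[1]) * nc[0] + ix[0];
  }
  void insert(int i, const vec3& p) {
    int c = cidx(p);
    cells[c].push_back(i);
    where[i] = c;
  }
  void remove(int i) {
    int c = where[i];
    auto& v = cells[c];
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == i) { v[k] = v.back(); v.pop_back(); break; }
    where[i] = -1;
  }
  void move(int i, const vec3& pnew) {
    remove(i);
    insert(i, pnew);
  }
  // visit candidate sites in the 27 cells around p (every site when brute)
  template <class F>
  void visit(const vec3& p, F f) const {
    if (brute) {
      for (int j : cells[0]) f(j);
      return;
    }
    const int* nb = &nbr27[(size_t)cidx(p) * 27];
    for (int t = 0; t < 27; ++t)
      for (int j : cells[nb[t]]) f(j);
  }
};

// hard-core cutoff squared with the documented numerical slack
inline double hard_core2(double sigma) {
  double h = sigma - 1e-12;
  return h * h;
}

inline vec3 get_row(const arma::mat& m, int i) {
  vec3 p;
  p[0] = m(i, 0); p[1] = m(i, 1); p[2] = m(i, 2);
  return p;
}

// uniform point on the unit sphere
inline vec3 rand_unit(std::mt19937_64& rng) {
  std::uniform_real_distribution<double> U(0.0, 1.0);
  double z = 2.0 * U(rng) - 1.0;
  double t = 2.0 * M_PI * U(rng);
  double r = std::sqrt(std::max(0.0, 1.0 - z * z));
  vec3 v;
  v[0] = r * std::cos(t); v[1] = r * std::sin(t); v[2] = z;
  return v;
}

// Rodrigues rotation of v about unit axis a by angle th
inline vec3 rotate_about(const vec3& v, const vec3& a, double th) {
  double c = std::cos(th), s = std::sin(th);
  return v * c + arma::cross(a, v) * s + a * arma::dot(a, v) * (1.0 - c);
}
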