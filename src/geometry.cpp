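// Validity checking, pair correlation and flipper mobility statistics.
#include "pack_common.h"
using namespace Rcpp;

// Full validity scan: non-bonded overlaps, bond-length violations.
// bonds: m x 2 matrix of 0-based site indices.
// [[Rcpp::export]]
List validate_cpp(const arma::mat& pos, NumericVector L, const arma::imat& bonds,
                  double sigma, double tol) {
  PBox box(L);
  int n = pos.n_rows;
  CellList cl;
  cl.init(box, n, sigma + tol + 1e-9);
  for (int i = 0; i < n; ++i) cl.insert(i, get_row(pos, i));

  // bonded pair lookup
  std::set<std::pair<int,int>> bset;
  for (arma::uword b = 0; b < bonds.n_rows; ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    bset.insert({std::min(i, j), std::max(i, j)});
  }
  double h2 = hard_core2(sigma);
  std::vector<int> oi, oj;
  std::vector<double> od;
  for (int i = 0; i < n; ++i) {
    vec3 p = get_row(pos, i);
    cl.visit(p, [&](int j) {
      if (j <= i) return;
      if (bset.count({i, j})) return;
      double d2 = box.dist2(p, get_row(pos, j));
      if (d2 < h2) {
        oi.push_back(i + 1); oj.push_back(j + 1); od.push_back(std::sqrt(d2));
      }
    });
  }
  std::vector<int> bi;
  std::vector<double> bl;
  for (arma::uword b = 0; b < bonds.n_rows; ++b) {
    double d = std::sqrt(box.dist2(get_row(pos, bonds(b, 0)), get_row(pos, bonds(b, 1))));
    if (d < sigma - 1e-12 || d > sigma + tol + 1e-12) {
      bi.push_back((int)b + 1); bl.push_back(d);
    }
  }
  return List::create(_["overlap_i"] = oi, _["overlap_j"] = oj, _["overlap_d"] = od,
                      _["bad_bond"] = bi, _["bad_bond_len"] = bl);
}

// Pair histogram for g(r): counts of unordered pairs per bin of width dr up to rmax.
// [[Rcpp::export]]
NumericVector gr_count_cpp(const arma::mat& pos, NumericVector L, double dr, double rmax) {
  PBox box(L);
  int n = pos.n_rows;
  int nb = (int)std::ceil(rmax / dr);
  NumericVector counts(nb);
  for (int i = 0; i < n; ++i) {
    vec3 p = get_row(pos, i);
    for (int j = i + 1; j < n; ++j) {
      double d2 = box.dist2(p, get_row(pos, j));
      if (d2 < rmax * rmax) {
        int b = (int)(std::sqrt(d2) / dr);
        if (b < nb) counts[b] += 1.0;
      }
    }
  }
  return counts;
}

// Flipper test: an interior site is a flipper at amplitude dphi (degrees) if
// rotating it about the axis through its two bonded neighbours by +dphi and
// by -dphi is overlap-free both ways.  prv/nxt are 0-based, -1 when absent.
// [[Rcpp::export]]
List flipper_cpp(const arma::mat& pos, NumericVector L, IntegerVector prv,
                 IntegerVector nxt, NumericVector dphi_deg, double sigma) {
  PBox box(L);
  int n = pos.n_rows;
  CellList cl;
  cl.init(box, n, sigma + 1e-9);
  for (int i = 0; i < n; ++i) cl.insert(i, get_row(pos, i));
  double h2 = hard_core2(sigma);
  int namp = dphi_deg.size();
  IntegerVector nflip(namp);
  int eligible = 0;

  auto free_at = [&](const vec3& p, int self) {
    bool ok = true;
    cl.visit(p, [&](int j) {
      if (!ok || j == self) return;
      if (box.dist2(p, get_row(pos, j)) < h2) ok = false;
    });
    return ok;
  };

  for (int s = 0; s < n; ++s) {
    if (prv[s] < 0 || nxt[s] < 0) continue;
    ++eligible;
    vec3 pp = get_row(pos, prv[s]);
    vec3 ax = box.minimg(get_row(pos, nxt[s]) - pp);
    double na = arma::norm(ax);
    if (na < 1e-14) continue;  // degenerate axis, counted eligible but immobile
    ax /= na;
    vec3 v = box.minimg(get_row(pos, s) - pp);
    for (int a = 0; a < namp; ++a) {
      double th = dphi_deg[a] * M_PI / 180.0;
      vec3 p1 = box.wrap(pp + rotate_about(v, ax, th));
      vec3 p2 = box.wrap(pp + rotate_about(v, ax, -th));
      if (free_at(p1, s) && free_at(p2, s)) nflip[a] += 1;
    }
  }
  return List::create(_["n_flippers"] = nflip, _["eligible"] = eligible);
}
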