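// Characteristic-crystallographic-element norm.
//
// For a site with first-shell vectors u_i (unit directions scaled by
// d_i / dbar, restoring radial sensitivity) and a reference structure X with
// ideal shell s_i and distinguishing point-group operations {g_k}, the norm is
//
//   eps^X = sqrt( min_R [ C(u, R s) + sum_k C(R g_k R^T u, u) ] / (n (1+m)) )
//
// where C(a, b) is the optimal-assignment sum of squared differences.  The
// rotation R is minimized by iterative closest point (assignment + Kabsch)
// from a deterministic low-discrepancy set of starting orientations, refined
// by Nelder-Mead on the full objective.  eps = 0 exactly for a perfect shell.
#include "pack_common.h"
using namespace Rcpp;

namespace {

// Hungarian algorithm (Jonker-Volgenant potentials), square cost matrix.
double hungarian(const arma::mat& a, std::vector<int>& col_of_row) {
  int n = a.n_rows;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j)
        if (!used[j]) {
          double cur = a(i0 - 1, j - 1) - u[i0] - v[j];
          if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
          if (minv[j] < delta) { delta = minv[j]; j1 = j; }
        }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  col_of_row.assign(n, -1);
  double cost = 0.0;
  for (int j = 1; j <= n; ++j) {
    col_of_row[p[j] - 1] = j - 1;
    cost += a(p[j] - 1, j - 1);
  }
  return cost;
}

arma::mat pair_cost(const arma::mat& A, const arma::mat& B) {
  int n = A.n_rows;
  arma::mat c(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = A(i, k) - B(j, k);
        s += d * d;
      }
      c(i, j) = s;
    }
  return c;
}

double assign_cost(const arma::mat& A, const arma::mat& B, std::vector<int>* perm = nullptr) {
  std::vector<int> pm;
  double c = hungarian(pair_cost(A, B), pm);
  if (perm) *perm = pm;
  return c;
}

// full objective: template match + symmetry closure, per vector per term
double objective(const arma::mat& U, const arma::mat& S,
                 const std::vector<arma::mat33>& ops, const arma::mat33& R) {
  int n = U.n_rows;
  double tot = assign_cost(U, S * R.t());
  for (const auto& g : ops) {
    arma::mat33 M = R * g * R.t();
    tot += assign_cost(U * M.t(), U);
  }
  return tot / (n * (1.0 + ops.size()));
}

// ICP on the template term only: alternate assignment and Kabsch
arma::mat33 icp(const arma::mat& U, const arma::mat& S, arma::mat33 R) {
  for (int it = 0; it < 80; ++it) {
    std::vector<int> perm;
    assign_cost(U, S * R.t(), &perm);
    arma::mat33 H = arma::zeros(3, 3);
    for (int i = 0; i < (int)perm.size(); ++i)
      H += S.row(perm[i]).t() * U.row(i);
    arma::mat Usv, Vsv;
    arma::vec ssv;
    arma::svd(Usv, ssv, Vsv, arma::mat(H));
    double d = arma::det(Vsv * Usv.t());
    arma::mat33 Rn = Vsv * arma::diagmat(arma::vec({1.0, 1.0, d})) * Usv.t();
    if (arma::abs(Rn - R).max() < 1e-13) return Rn;
    R = Rn;
  }
  return R;
}

arma::mat33 rotvec_mat(const vec3& w) {
  double th = arma::norm(w);
  arma::mat33 I = arma::eye(3, 3);
  if (th < 1e-14) return I;
  vec3 a = w / th;
  arma::mat33 K = arma::zeros(3, 3);
  K(0, 1) = -a[2]; K(0, 2) = a[1];
  K(1, 0) = a[2];  K(1, 2) = -a[0];
  K(2, 0) = -a[1]; K(2, 1) = a[0];
  return I + std::sin(th) * K + (1.0 - std::cos(th)) * K * K;
}

// Nelder-Mead over a rotation-vector perturbation about R0
double nelder_mead(const arma::mat& U, const arma::mat& S,
                   const std::vector<arma::mat33>& ops, const arma::mat33& R0,
                   int maxit) {
  auto f = [&](const vec3& w) { return objective(U, S, ops, rotvec_mat(w) * R0); };
  const int d = 3;
  std::vector<vec3> x(d + 1);
  std::vector<double> fx(d + 1);
  x[0] = arma::zeros<arma::vec>(3);
  for (int i = 1; i <= d; ++i) {
    x[i] = arma::zeros<arma::vec>(3);
    x[i][i - 1] = 0.15;
  }
  for (int i = 0; i <= d; ++i) fx[i] = f(x[i]);
  for (int it = 0; it < maxit; ++it) {
    // order
    std::vector<int> idx = {0, 1, 2, 3};
    std::sort(idx.begin(), idx.end(), [&](int a, int b) { return fx[a] < fx[b]; });
    std::vector<vec3> xs(d + 1);
    std::vector<double> fs(d + 1);
    for (int i = 0; i <= d; ++i) { xs[i] = x[idx[i]]; fs[i] = fx[idx[i]]; }
    x = xs; fx = fs;
    if (fx[d] - fx[0] < 1e-15) break;
    vec3 c = (x[0] + x[1] + x[2]) / 3.0;
    vec3 xr = c + (c - x[d]);
    double fr = f(xr);
    if (fr < fx[0]) {
      vec3 xe = c + 2.0 * (c - x[d]);
      double fe = f(xe);
      if (fe < fr) { x[d] = xe; fx[d] = fe; }
      else { x[d] = xr; fx[d] = fr; }
    } else if (fr < fx[d - 1]) {
      x[d] = xr; fx[d] = fr;
    } else {
      vec3 xc = c + 0.5 * (x[d] - c);
      double fc = f(xc);
      if (fc < fx[d]) { x[d] = xc; fx[d] = fc; }
      else {
        for (int i = 1; i <= d; ++i) {
          x[i] = x[0] + 0.5 * (x[i] - x[0]);
          fx[i] = f(x[i]);
        }
      }
    }
  }
  return *std::min_element(fx.begin(), fx.end());
}

// deterministic low-discrepancy rotations (Shoemake quaternions)
std::vector<arma::mat33> start_rotations(int n) {
  std::vector<arma::mat33> out;
  out.push_back(arma::eye(3, 3));
  auto frac = [](double x) { return x - std::floor(x); };
  for (int t = 1; t < n; ++t) {
    double u1 = frac(0.5 + t * 0.6180339887498949);
    double u2 = frac(0.5 + t * 0.7548776662466927);
    double u3 = frac(0.5 + t * 0.5698402909980532);
    double q0 = std::sqrt(1 - u1) * std::sin(2 * M_PI * u2);
    double q1 = std::sqrt(1 - u1) * std::cos(2 * M_PI * u2);
    double q2 = std::sqrt(u1) * std::sin(2 * M_PI * u3);
    double q3 = std::sqrt(u1) * std::cos(2 * M_PI * u3);
    arma::mat33 R;
    R(0, 0) = 1 - 2 * (q2 * q2 + q3 * q3);
    R(0, 1) = 2 * (q1 * q2 - q0 * q3);
    R(0, 2) = 2 * (q1 * q3 + q0 * q2);
    R(1, 0) = 2 * (q1 * q2 + q0 * q3);
    R(1, 1) = 1 - 2 * (q1 * q1 + q3 * q3);
    R(1, 2) = 2 * (q2 * q3 - q0 * q1);
    R(2, 0) = 2 * (q1 * q3 - q0 * q2);
    R(2, 1) = 2 * (q2 * q3 + q0 * q1);
    R(2, 2) = 1 - 2 * (q1 * q1 + q2 * q2);
    out.push_back(R);
  }
  return out;
}

double cce_one(const arma::mat& U, const arma::mat& S,
               const std::vector<arma::mat33>& ops, int n_starts, int n_refine,
               int nm_maxit) {
  static std::vector<arma::mat33> starts;  // cache, deterministic
  if ((int)starts.size() < n_starts) starts = start_rotations(n_starts);
  std::vector<std::pair<double, arma::mat33>> cand;
  for (int t = 0; t < n_starts; ++t) {
    arma::mat33 R = icp(U, S, starts[t]);
    cand.push_back({objective(U, S, ops, R), R});
  }
  std::sort(cand.begin(), cand.end(),
            [](const auto& a, const auto& b) { return a.first < b.first; });
  double best = cand[0].first;
  if (best < 1e-20) return std::sqrt(std::max(0.0, best));
  for (int t = 0; t < std::min(n_refine, (int)cand.size()); ++t)
    best = std::min(best, nelder_mead(U, S, ops, cand[t].second, nm_maxit));
  return std::sqrt(std::max(0.0, best));
}

std::vector<arma::mat33> ops_from_list(const List& opl) {
  std::vector<arma::mat33> ops;
  for (int k = 0; k < opl.size(); ++k) {
    arma::mat m = as<arma::mat>(opl[k]);
    arma::mat33 g;
    for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) g(i, j) = m(i, j);
    ops.push_back(g);
  }
  return ops;
}

}  // namespace

// Norm of an explicit shell of vectors (rows of U, already scaled) against a
// template; used for template fixtures and cross-checks.
// [[Rcpp::export]]
double cce_shell_cpp(const arma::mat& U, const arma::mat& S, List ops,
                     int n_starts = 40, int n_refine = 4, int nm_maxit = 250) {
  return cce_one(U, S, ops_from_list(ops), n_starts, n_refine, nm_maxit);
}

// Per-site norms for a configuration.  sites: 0-based indices to evaluate.
// templates: list of n x 3 matrices; opsets: parallel list of lists of 3x3.
// Neighbour shell: the k_nn nearest minimum-image neighbours; sites with
// fewer than k_nn available neighbours get +Inf.
// [[Rcpp::export]]
arma::mat cce_cpp(const arma::mat& pos, NumericVector L, IntegerVector sites,
                  List templates, List opsets, int k_nn = 12, int n_starts = 40,
                  int n_refine = 4, int nm_maxit = 250) {
  PBox box(L);
  int n = pos.n_rows;
  int ns = sites.size(), nt = templates.size();
  std::vector<arma::mat> tmpl(nt);
  std::vector<std::vector<arma::mat33>> ops(nt);
  for (int t = 0; t < nt; ++t) {
    tmpl[t] = as<arma::mat>(templates[t]);
    ops[t] = ops_from_list(as<List>(opsets[t]));
  }
  arma::mat out(ns, nt);
  std::vector<std::pair<double, int>> d2(n);
  for (int si = 0; si < ns; ++si) {
    int i = sites[si];
    vec3 pi = get_row(pos, i);
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      d2[m++] = {box.dist2(pi, get_row(pos, j)), j};
    }
    if (m < k_nn) {
      out.row(si).fill(arma::datum::inf);
      continue;
    }
    std::partial_sort(d2.begin(), d2.begin() + k_nn, d2.begin() + m);
    arma::mat U(k_nn, 3);
    double dbar = 0.0;
    for (int k = 0; k < k_nn; ++k) dbar += std::sqrt(d2[k].first);
    dbar /= k_nn;
    for (int k = 0; k < k_nn; ++k) {
      vec3 r = box.minimg(get_row(pos, d2[k].second) - pi) / dbar;
      for (int c = 0; c < 3; ++c) U(k, c) = r[c];
    }
    for (int t = 0; t < nt; ++t)
      out(si, t) = cce_one(U, tmpl[t], ops[t], n_starts, n_refine, nm_maxit);
  }
  return out;
}
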