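// Monte Carlo engine for freely-jointed tangent hard-sphere chains.
//
// Move mix: reptation, end rotation, configurational-bias end regrowth,
// inter-chain reptation, internal libration, simplified end-bridging (sEB)
// and its intramolecular analog (sIEB).  Local moves use the multiple-trial
// (Rosenbluth) pattern; connectivity-altering moves additionally carry the
// chain-length chemical-potential weight of the fixed-(n_at, n_ch, V) ensemble.
// Chains of length one fall back to displacement / multi-trial reinsertion,
// which is the monomer simulation mode.
#include "pack_common.h"
using namespace Rcpp;

namespace {

enum Move { REPT = 0, ENDROT, CB, ICHR, LIB, SEB, SIEB, DISP, NMOVE };

struct Engine {
  PBox box;
  double sigma, tol, bond_len, h2;
  arma::mat pos;
  std::vector<std::vector<int>> chains;
  std::vector<int> chain_of, idx_in;
  CellList cl;
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> U{0.0, 1.0};

  int k_trials, max_regrow, Nmin, Nmax;
  double delta_lib, delta_disp, r_search;
  bool autotune = true;
  long long lib_att_w = 0, lib_acc_w = 0, disp_att_w = 0, disp_acc_w = 0;
  std::vector<double> mu;  // mu[N], 1-based on length
  double cum[7];

  long long att[NMOVE] = {0}, acc[NMOVE] = {0};

  Engine(const arma::mat& pos_, const List& chains_, NumericVector L,
         double sigma_, double tol_, int seed)
      : box(L), sigma(sigma_), tol(tol_), pos(pos_), rng((unsigned long long)seed) {
    bond_len = sigma + 0.5 * tol;
    h2 = hard_core2(sigma);
    int n = pos.n_rows;
    chain_of.assign(n, -1);
    idx_in.assign(n, -1);
    for (int c = 0; c < chains_.size(); ++c) {
      IntegerVector ch = chains_[c];
      std::vector<int> v(ch.size());
      for (int k = 0; k < ch.size(); ++k) v[k] = ch[k] - 1;
      chains.push_back(v);
    }
    reindex_all();
    cl.init(box, n, 1.1 * sigma + tol);
    for (int i = 0; i < n; ++i) cl.insert(i, get_row(pos, i));
  }

  void reindex_all() {
    for (size_t c = 0; c < chains.size(); ++c) reindex(c);
  }
  void reindex(int c) {
    for (size_t k = 0; k < chains[c].size(); ++k) {
      chain_of[chains[c][k]] = c;
      idx_in[chains[c][k]] = (int)k;
    }
  }

  inline vec3 site(int i) const { return get_row(pos, i); }
  inline void set_site(int i, const vec3& p) {
    pos(i, 0) = p[0]; pos(i, 1) = p[1]; pos(i, 2) = p[2];
  }

  bool free_pos(const vec3& p) {
    bool ok = true;
    cl.visit(p, [&](int j) {
      if (!ok) return;
      if (box.dist2w(p, site(j)) < h2) ok = false;
    });
    return ok;
  }

  inline int ri(int n) { return (int)(U(rng) * n) % n; }

  vec3 sphere_trial(const vec3& center) {
    return box.wrap(center + bond_len * rand_unit(rng));
  }

  // count feasible among k-1 fresh trials around center, plus the old position
  int weight_old_sphere(const vec3& center) {
    int W = 1;
    for (int t = 0; t < k_trials - 1; ++t)
      if (free_pos(sphere_trial(center))) ++W;
    return W;
  }
  // k fresh trials; uniform choice among feasible; W = 0 when none
  int weight_new_sphere(const vec3& center, vec3& chosen) {
    int W = 0;
    for (int t = 0; t < k_trials; ++t) {
      vec3 p = sphere_trial(center);
      if (free_pos(p)) {
        ++W;
        if (U(rng) < 1.0 / W) chosen = p;
      }
    }
    return W;
  }

  // circle of points at bond_len from both a and b
  bool circle_basis(const vec3& a, const vec3& b, vec3& center, vec3& e1,
                    vec3& e2, double& r) {
    vec3 d = box.minimg(b - a);
    double D = arma::norm(d);
    if (D >= 2.0 * bond_len || D < 1e-12) return false;
    vec3 dh = d / D;
    center = a + 0.5 * d;
    r = std::sqrt(bond_len * bond_len - 0.25 * D * D);
    vec3 t = arma::zeros<arma::vec>(3);
    int kmin = (std::fabs(dh[0]) <= std::fabs(dh[1]) && std::fabs(dh[0]) <= std::fabs(dh[2])) ? 0
             : (std::fabs(dh[1]) <= std::fabs(dh[2]) ? 1 : 2);
    t[kmin] = 1.0;
    e1 = t - dh * arma::dot(dh, t);
    e1 /= arma::norm(e1);
    e2 = arma::cross(dh, e1);
    return true;
  }
  vec3 circle_trial(const vec3& center, const vec3& e1, const vec3& e2, double r) {
    double th = 2.0 * M_PI * U(rng);
    return box.wrap(center + r * (std::cos(th) * e1 + std::sin(th) * e2));
  }
  // a trial on the tangency circle must also realize both bond lengths
  // under the minimum image (guards against folded geometry in small boxes)
  bool circle_ok(const vec3& p, const vec3& a, const vec3& b) {
    double da = std::sqrt(box.dist2(p, a)), db = std::sqrt(box.dist2(p, b));
    return std::fabs(da - bond_len) < 1e-9 && std::fabs(db - bond_len) < 1e-9;
  }
  int weight_old_circle(const vec3& a, const vec3& b) {
    vec3 c, e1, e2; double r;
    if (!circle_basis(a, b, c, e1, e2, r)) return 1;  // old position only
    int W = 1;
    for (int t = 0; t < k_trials - 1; ++t) {
      vec3 p = circle_trial(c, e1, e2, r);
      if (circle_ok(p, a, b) && free_pos(p)) ++W;
    }
    return W;
  }
  int weight_new_circle(const vec3& a, const vec3& b, vec3& chosen) {
    vec3 c, e1, e2; double r;
    if (!circle_basis(a, b, c, e1, e2, r)) return 0;
    int W = 0;
    for (int t = 0; t < k_trials; ++t) {
      vec3 p = circle_trial(c, e1, e2, r);
      if (circle_ok(p, a, b) && free_pos(p)) {
        ++W;
        if (U(rng) < 1.0 / W) chosen = p;
      }
    }
    return W;
  }

  double mu_of(int N) {
    if (mu.empty()) return 0.0;
    int i = std::min((int)mu.size() - 1, std::max(1, N));
    return mu[i];
  }

  // ---- moves ----------------------------------------------------------

  // keep amplitude in the 30-50% acceptance window
  void tune(long long& att_w, long long& acc_w, bool ok, double& delta,
            double lo, double hi) {
    ++att_w;
    if (ok) ++acc_w;
    if (autotune && att_w >= 2000) {
      double rate = (double)acc_w / att_w;
      if (rate < 0.30) delta *= 0.8;
      else if (rate > 0.50) delta *= 1.25;
      delta = std::min(hi, std::max(lo, delta));
      att_w = acc_w = 0;
    }
  }

  bool displacement(int s) {
    ++att[DISP];
    vec3 p = site(s), q;
    for (int k = 0; k < 3; ++k) q[k] = p[k] + (2.0 * U(rng) - 1.0) * delta_disp;
    q = box.wrap(q);
    cl.remove(s);
    bool ok = free_pos(q);
    if (ok) { set_site(s, q); cl.insert(s, q); ++acc[DISP]; }
    else cl.insert(s, p);
    tune(disp_att_w, disp_acc_w, ok, delta_disp, 1e-4, 0.5);
    return ok;
  }

  // multi-trial reinsertion anywhere in the box (monomer configurational bias)
  bool reinsertion(int s) {
    ++att[DISP];
    vec3 old = site(s);
    cl.remove(s);
    int Wo = 1;
    for (int t = 0; t < k_trials - 1; ++t) {
      vec3 p;
      for (int k = 0; k < 3; ++k) p[k] = U(rng) * box.L[k];
      if (free_pos(p)) ++Wo;
    }
    vec3 chosen;
    int Wn = 0;
    for (int t = 0; t < k_trials; ++t) {
      vec3 p;
      for (int k = 0; k < 3; ++k) p[k] = U(rng) * box.L[k];
      if (free_pos(p)) {
        ++Wn;
        if (U(rng) < 1.0 / Wn) chosen = p;
      }
    }
    if (Wn > 0 && U(rng) < (double)Wn / Wo) {
      set_site(s, chosen); cl.insert(s, chosen); ++acc[DISP];
      return true;
    }
    cl.insert(s, old);
    return false;
  }

  bool reptation(int c) {
    ++att[REPT];
    auto& ch = chains[c];
    int len = (int)ch.size();
    bool from_head = U(rng) < 0.5;
    int s = from_head ? ch.front() : ch.back();
    int u = from_head ? ch[1] : ch[len - 2];          // old bonded neighbour
    int t = from_head ? ch.back() : ch.front();       // new anchor (other end)
    vec3 old = site(s);
    cl.remove(s);
    int Wo = weight_old_sphere(site(u));
    vec3 chosen;
    int Wn = weight_new_sphere(site(t), chosen);
    if (Wn > 0 && U(rng) < (double)Wn / Wo) {
      set_site(s, chosen); cl.insert(s, chosen);
      if (from_head) { ch.erase(ch.begin()); ch.push_back(s); }
      else { ch.pop_back(); ch.insert(ch.begin(), s); }
      reindex(c);
      bonded_dirty = true;
      ++acc[REPT];
      return true;
    }
    cl.insert(s, old);
    return false;
  }

  bool end_rotation(int c) {
    ++att[ENDROT];
    auto& ch = chains[c];
    int len = (int)ch.size();
    bool from_head = U(rng) < 0.5;
    int s = from_head ? ch.front() : ch.back();
    int u = from_head ? ch[1] : ch[len - 2];
    vec3 old = site(s), anchor = site(u);
    cl.remove(s);
    int Wo = weight_old_sphere(anchor);
    vec3 chosen;
    int Wn = weight_new_sphere(anchor, chosen);
    if (Wn > 0 && U(rng) < (double)Wn / Wo) {
      set_site(s, chosen); cl.insert(s, chosen); ++acc[ENDROT];
      return true;
    }
    cl.insert(s, old);
    return false;
  }

  bool config_bias(int c) {
    ++att[CB];
    auto& ch = chains[c];
    int len = (int)ch.size();
    int mmax = std::min(max_regrow, len - 1);
    int m = 1 + ri(mmax);
    bool from_head = U(rng) < 0.5;
    // sites outermost-first: sg[0] = end ... sg[m-1] = innermost regrown
    std::vector<int> sg(m);
    for (int j = 0; j < m; ++j) sg[j] = from_head ? ch[j] : ch[len - 1 - j];
    int anchor = from_head ? ch[m] : ch[len - 1 - m];
    std::vector<vec3> old(m);
    for (int j = 0; j < m; ++j) { old[j] = site(sg[j]); cl.remove(sg[j]); }
    // old weights, innermost first, re-inserting as we go
    double Wo = 1.0;
    for (int j = m - 1; j >= 0; --j) {
      vec3 center = (j == m - 1) ? site(anchor) : old[j + 1];
      Wo *= weight_old_sphere(center);
      cl.insert(sg[j], old[j]);
    }
    // new growth
    for (int j = 0; j < m; ++j) cl.remove(sg[j]);
    double Wn = 1.0;
    int placed = 0;
    std::vector<vec3> fresh(m);
    bool fail = false;
    for (int j = m - 1; j >= 0; --j) {
      vec3 center = (j == m - 1) ? site(anchor) : fresh[j + 1];
      vec3 chosen;
      int W = weight_new_sphere(center, chosen);
      if (W == 0) { fail = true; break; }
      Wn *= W;
      fresh[j] = chosen;
      set_site(sg[j], chosen);
      cl.insert(sg[j], chosen);
      ++placed;
    }
    if (!fail && U(rng) < Wn / Wo) { ++acc[CB]; return true; }
    // revert
    for (int j = m - 1; j >= m - placed; --j) cl.remove(sg[j]);
    for (int j = 0; j < m; ++j) { set_site(sg[j], old[j]); cl.insert(sg[j], old[j]); }
    return false;
  }

  bool interchain_reptation(int a) {
    ++att[ICHR];
    int n_ch = (int)chains.size();
    if (n_ch < 2) return false;
    int b = ri(n_ch - 1);
    if (b >= a) ++b;
    int la = (int)chains[a].size(), lb = (int)chains[b].size();
    if (la - 1 < Nmin || lb + 1 > Nmax) return false;
    auto& cha = chains[a];
    auto& chb = chains[b];
    bool from_head = U(rng) < 0.5;
    int s = from_head ? cha.front() : cha.back();
    int u = (la >= 2) ? (from_head ? cha[1] : cha[la - 2]) : -1;
    bool to_head = U(rng) < 0.5;
    int t = to_head ? chb.front() : chb.back();
    vec3 old = site(s);
    cl.remove(s);
    int Wo = (u >= 0) ? weight_old_sphere(site(u)) : 1;
    vec3 chosen;
    int Wn = weight_new_sphere(site(t), chosen);
    double mufac = std::exp(mu_of(la - 1) + mu_of(lb + 1) - mu_of(la) - mu_of(lb));
    if (Wn > 0 && U(rng) < (double)Wn / Wo * mufac) {
      set_site(s, chosen); cl.insert(s, chosen);
      if (from_head) cha.erase(cha.begin()); else cha.pop_back();
      if (to_head) chb.insert(chb.begin(), s); else chb.push_back(s);
      reindex(a); reindex(b);
      bonded_dirty = true;
      ++acc[ICHR];
      return true;
    }
    cl.insert(s, old);
    return false;
  }

  bool libration(int s) {
    ++att[LIB];
    int c = chain_of[s], j = idx_in[s];
    auto& ch = chains[c];
    if (j == 0 || j == (int)ch.size() - 1) return false;
    vec3 pp = site(ch[j - 1]);
    vec3 ax = box.minimg(site(ch[j + 1]) - pp);
    double na = arma::norm(ax);
    if (na < 1e-12) return false;
    ax /= na;
    vec3 v = box.minimg(site(s) - pp);
    double th = (2.0 * U(rng) - 1.0) * delta_lib;
    vec3 q = box.wrap(pp + rotate_about(v, ax, th));
    vec3 old = site(s);
    vec3 pn = site(ch[j + 1]);
    double d_prv = std::sqrt(box.dist2(old, pp)), d_nxt = std::sqrt(box.dist2(old, pn));
    cl.remove(s);
    bool ok = std::fabs(std::sqrt(box.dist2(q, pp)) - d_prv) < 1e-9 &&
              std::fabs(std::sqrt(box.dist2(q, pn)) - d_nxt) < 1e-9 &&
              free_pos(q);
    if (ok) { set_site(s, q); cl.insert(s, q); ++acc[LIB]; }
    else cl.insert(s, old);
    tune(lib_att_w, lib_acc_w, ok, delta_lib, 1e-4, M_PI);
    return ok;
  }

  // candidates for end-bridging: non-bonded interior spheres near an end
  std::vector<int> bridge_candidates(int e, int own_chain, bool same_chain) {
    std::vector<int> cand;
    vec3 pe = site(e);
    double rmax = sigma + tol + r_search;
    cl.visit(pe, [&](int j) {
      if (j == e) return;
      int c = chain_of[j];
      if (same_chain ? (c != own_chain) : (c == own_chain)) return;
      int k = idx_in[j];
      if (k == 0 || k == (int)chains[c].size() - 1) return;  // interior only
      if (same_chain && std::abs(k - idx_in[e]) < 2) return; // not bonded to e
      double d2 = box.dist2(pe, site(j));
      if (d2 <= rmax * rmax) cand.push_back(j);
    });
    return cand;
  }

  bool seb(int a) {
    ++att[SEB];
    auto& cha = chains[a];
    bool e_head = U(rng) < 0.5;
    int e = e_head ? cha.front() : cha.back();
    std::vector<int> cand = bridge_candidates(e, a, false);
    if (cand.empty()) return false;
    int s = cand[ri((int)cand.size())];
    int b = chain_of[s], j = idx_in[s];
    auto& chb = chains[b];
    int lb = (int)chb.size(), la = (int)cha.size();
    int u = chb[j - 1], v = chb[j + 1];
    // option 1: delete u-s, transfer [s..back]; option 2: delete v-s, transfer [front..s]
    int tr1 = lb - j, tr2 = j + 1;
    bool ok1 = (la + tr1 <= Nmax && lb - tr1 >= Nmin);
    bool ok2 = (la + tr2 <= Nmax && lb - tr2 >= Nmin);
    if (!ok1 && !ok2) return false;
    bool opt1 = ok1 && (!ok2 || U(rng) < 0.5);
    int udel = opt1 ? u : v;  // deleted-bond neighbour
    int w = opt1 ? v : u;     // kept neighbour
    vec3 old = site(s);
    cl.remove(s);
    int Wo = weight_old_circle(site(udel), site(w));
    vec3 chosen;
    int Wn = weight_new_circle(site(e), site(w), chosen);
    int tr = opt1 ? tr1 : tr2;
    double mufac = std::exp(mu_of(la + tr) + mu_of(lb - tr) - mu_of(la) - mu_of(lb));
    if (Wn > 0 && U(rng) < (double)Wn / Wo * mufac) {
      set_site(s, chosen); cl.insert(s, chosen);
      // splice the transferred segment onto chain a at end e
      std::vector<int> seg;  // ordered starting at s, moving away from udel
      if (opt1) for (int k = j; k < lb; ++k) seg.push_back(chb[k]);
      else for (int k = j; k >= 0; --k) seg.push_back(chb[k]);
      std::vector<int> rest;
      if (opt1) for (int k = 0; k < j; ++k) rest.push_back(chb[k]);
      else for (int k = j + 1; k < lb; ++k) rest.push_back(chb[k]);
      if (e_head) {  // prepend reversed segment so s sits next to e
        std::vector<int> na(seg.rbegin(), seg.rend());
        na.insert(na.end(), cha.begin(), cha.end());
        cha = na;
      } else {
        cha.insert(cha.end(), seg.begin(), seg.end());
      }
      chb = rest;
      reindex(a); reindex(b);
      bonded_dirty = true;
      ++acc[SEB];
      return true;
    }
    cl.insert(s, old);
    return false;
  }

  bool sieb(int a) {
    ++att[SIEB];
    auto& ch = chains[a];
    int len = (int)ch.size();
    if (len < 4) return false;
    bool e_head = U(rng) < 0.5;
    if (!e_head) std::reverse(ch.begin(), ch.end()), reindex(a);  // canonical: e at front
    int e = ch[0];
    std::vector<int> cand = bridge_candidates(e, a, true);
    if (cand.empty()) {
      if (!e_head) std::reverse(ch.begin(), ch.end()), reindex(a);
      return false;
    }
    int s = cand[ri((int)cand.size())];
    int j = idx_in[s];
    int u = ch[j - 1], v = ch[j + 1];
    vec3 old = site(s);
    cl.remove(s);
    int Wo = weight_old_circle(site(u), site(v));
    vec3 chosen;
    int Wn = weight_new_circle(site(e), site(v), chosen);
    bool accepted = (Wn > 0 && U(rng) < (double)Wn / Wo);
    if (accepted) {
      set_site(s, chosen); cl.insert(s, chosen);
      // new chain: [c_{j-1} .. c_0, s, c_{j+1} .. ]
      std::vector<int> nc;
      for (int k = j - 1; k >= 0; --k) nc.push_back(ch[k]);
      nc.push_back(s);
      for (int k = j + 1; k < len; ++k) nc.push_back(ch[k]);
      ch = nc;
      bonded_dirty = true;
      ++acc[SIEB];
    } else {
      cl.insert(s, old);
    }
    if (!e_head) std::reverse(ch.begin(), ch.end());
    reindex(a);
    return accepted;
  }

  void one_step() {
    double u = U(rng);
    int mv = 0;
    while (mv < 6 && u >= cum[mv]) ++mv;
    int n_ch = (int)chains.size();
    int c = ri(n_ch);
    int len = (int)chains[c].size();
    if (len == 1) {  // monomer mode
      if (mv == CB) reinsertion(chains[c][0]);
      else displacement(chains[c][0]);
      return;
    }
    switch (mv) {
      case REPT: reptation(c); break;
      case ENDROT: end_rotation(c); break;
      case CB: config_bias(c); break;
      case ICHR: interchain_reptation(c); break;
      case LIB: {
        int s = chains[c][ri(len)];
        libration(s);
        break;
      }
      case SEB: seb(c); break;
      case SIEB: sieb(c); break;
    }
  }

  double phi() const {
    return pos.n_rows * (M_PI / 6.0) * sigma * sigma * sigma / box.volume();
  }

  // isotropic shrink with rigid affine repositioning of each chain by its
  // head.  Chains translate rigidly, so pair displacements are not a pure
  // scaling; the trial configuration is scanned with its own cell list.
  std::set<std::pair<int,int>> bonded_set;
  bool bonded_dirty = true;
  arma::mat shrink_np;   // scratch buffers reused across shrink attempts
  CellList shrink_cl;
  void refresh_bonds() {
    bonded_set.clear();
    for (auto& ch : chains)
      for (size_t k = 0; k + 1 < ch.size(); ++k)
        bonded_set.insert({std::min(ch[k], ch[k + 1]), std::max(ch[k], ch[k + 1])});
    bonded_dirty = false;
  }

  // smallest non-bonded pair distance (squared) in the current state
  double min_pair_dist() {
    if (bonded_dirty) refresh_bonds();
    int n = pos.n_rows;
    double best = std::numeric_limits<double>::infinity();
    for (int i = 0; i < n; ++i) {
      vec3 pi = site(i);
      cl.visit(pi, [&](int j) {
        if (j <= i) return;
        double d2 = box.dist2w(pi, site(j));
        if (d2 < best && !bonded_set.count({i, j})) best = d2;
      });
    }
    return std::sqrt(best);
  }

  bool monomeric() const {
    for (auto& ch : chains) if (ch.size() != 1) return false;
    return true;
  }

  // exact shrink for monomers: distances scale by f, so the largest legal
  // factor follows directly from the minimum gap
  bool shrink_exact(double f_needed) {
    double dmin = min_pair_dist();
    double f_gap = (sigma - 0.5e-12) / dmin;
    double f = std::max(f_needed, std::max(f_gap, 0.95));
    if (f >= 1.0 - 1e-12) return false;  // in contact: relax first
    int n = pos.n_rows;
    for (int i = 0; i < n; ++i) {
      vec3 p = site(i) * f;
      set_site(i, p);
    }
    for (int k = 0; k < 3; ++k) box.L[k] *= f;
    for (int i = 0; i < n; ++i) set_site(i, box.wrap(site(i)));
    cl.init(box, n, 1.1 * sigma + tol);
    for (int i = 0; i < n; ++i) cl.insert(i, site(i));
    return true;
  }

  bool try_shrink(double f) {
    if (f < 0.95) f = 0.95;
    int n = pos.n_rows;
    if (bonded_dirty) refresh_bonds();
    PBox nbox = box;
    for (int k = 0; k < 3; ++k) nbox.L[k] *= f;
    if ((int)shrink_np.n_rows != n) shrink_np.set_size(n, 3);
    arma::mat& np = shrink_np;
    for (auto& ch : chains) {
      // unwrap the chain by following bonds, reposition its head affinely,
      // translate the unwrapped body with it, re-wrap in the shrunk box
      vec3 head = site(ch[0]);
      vec3 shift = (f - 1.0) * head;
      vec3 unwrapped = head;
      for (size_t k = 0; k < ch.size(); ++k) {
        if (k > 0) unwrapped += box.minimg(site(ch[k]) - site(ch[k - 1]));
        vec3 p = nbox.wrap(unwrapped + shift);
        np(ch[k], 0) = p[0]; np(ch[k], 1) = p[1]; np(ch[k], 2) = p[2];
      }
    }
    CellList& cl2 = shrink_cl;
    cl2.init(nbox, n, 1.1 * sigma + tol);
    for (int i = 0; i < n; ++i) cl2.insert(i, get_row(np, i));
    bool ok = true;
    for (int i = 0; i < n && ok; ++i) {
      vec3 pi_new = get_row(np, i);
      cl2.visit(pi_new, [&](int j) {
        if (!ok || j <= i) return;
        if (nbox.dist2w(pi_new, get_row(np, j)) < h2) {
          if (!bonded_set.count({i, j})) ok = false;
        }
      });
    }
    if (ok) {
      pos = np;
      box = nbox;
      cl.init(box, n, 1.1 * sigma + tol);
      for (int i = 0; i < n; ++i) cl.insert(i, site(i));
    }
    return ok;
  }

  List snapshot() const {
    List ch(chains.size());
    for (size_t c = 0; c < chains.size(); ++c) {
      IntegerVector v(chains[c].size());
      for (size_t k = 0; k < chains[c].size(); ++k) v[k] = chains[c][k] + 1;
      ch[c] = v;
    }
    return List::create(_["pos"] = pos, _["chains"] = ch,
                        _["L"] = NumericVector::create(box.L[0], box.L[1], box.L[2]));
  }

  List stats() const {
    NumericVector attempted(NMOVE), accepted(NMOVE);
    for (int m = 0; m < NMOVE; ++m) { attempted[m] = (double)att[m]; accepted[m] = (double)acc[m]; }
    return List::create(_["attempted"] = attempted, _["accepted"] = accepted);
  }
};

void set_params(Engine& E, const List& par) {
  NumericVector probs = par["probs"];
  double c = 0.0;
  for (int m = 0; m < 6; ++m) { c += probs[m]; E.cum[m] = c; }
  E.cum[6] = 1.0;
  E.k_trials = as<int>(par["k_trials"]);
  E.max_regrow = as<int>(par["max_regrow"]);
  E.delta_lib = as<double>(par["delta_lib"]);
  E.delta_disp = as<double>(par["delta_disp"]);
  E.r_search = as<double>(par["r_search"]);
  E.Nmin = as<int>(par["n_min"]);
  E.Nmax = as<int>(par["n_max"]);
  NumericVector muv = par["mu"];
  E.mu.assign(muv.begin(), muv.end());
  E.mu.insert(E.mu.begin(), 0.0);  // 1-based
}

}  // namespace

// [[Rcpp::export]]
List run_mc_cpp(const arma::mat& pos, List chains, NumericVector L, double sigma,
                double tol, double n_steps, List par, int seed,
                double record_every = 0, double length_every = 0,
                double gr_every = 0, double gr_dr = 0.02, double gr_rmax = 0) {
  Engine E(pos, chains, L, sigma, tol, seed);
  set_params(E, par);

  std::vector<List> frames;
  int lmax = (int)pos.n_rows;
  std::vector<double> len_counts(lmax + 1, 0.0);
  int grn = (gr_every > 0 && gr_rmax > 0) ? (int)std::ceil(gr_rmax / gr_dr) : 0;
  std::vector<double> gr_counts(grn, 0.0);
  double gr_samples = 0.0;
  long long nsteps = (long long)n_steps;
  long long rec = (long long)record_every, lev = (long long)length_every;
  long long gev = (long long)gr_every;

  for (long long step = 1; step <= nsteps; ++step) {
    E.one_step();
    if (rec > 0 && step % rec == 0)
      frames.push_back(E.snapshot());
    if (lev > 0 && step % lev == 0)
      for (auto& ch : E.chains) len_counts[std::min((size_t)lmax, ch.size())] += 1.0;
    if (grn > 0 && gev > 0 && step % gev == 0) {
      int n = E.pos.n_rows;
      for (int i = 0; i < n; ++i) {
        vec3 p = E.site(i);
        for (int j = i + 1; j < n; ++j) {
          double d2 = E.box.dist2(p, E.site(j));
          if (d2 < gr_rmax * gr_rmax) {
            int b = (int)(std::sqrt(d2) / gr_dr);
            if (b < grn) gr_counts[b] += 1.0;
          }
        }
      }
      gr_samples += 1.0;
    }
    if (step % 1000000LL == 0) Rcpp::checkUserInterrupt();
  }

  List fr(frames.size());
  for (size_t i = 0; i < frames.size(); ++i) fr[i] = frames[i];
  return List::create(
      _["state"] = E.snapshot(), _["stats"] = E.stats(),
      _["frames"] = fr, _["length_counts"] = wrap(len_counts),
      _["gr_counts"] = wrap(gr_counts), _["gr_samples"] = gr_samples,
      _["gr_dr"] = gr_dr);
}

// Compression towards a target packing fraction: alternate MC relaxation with
// isotropic shrink attempts; every chain is rigidly repositioned by the affine
// image of its first sphere.  Returns the (possibly partial) final state.
// [[Rcpp::export]]
List compress_cpp(const arma::mat& pos, List chains, NumericVector L, double sigma,
                  double tol, double phi_target, double shrink_factor,
                  double relax_steps, double max_cycles, List par, int seed) {
  Engine E(pos, chains, L, sigma, tol, seed);
  set_params(E, par);
  bool reached = false;
  long long cycles = 0, budget = (long long)max_cycles;
  long long relax = (long long)relax_steps;
  long long shrink_att = 0, shrink_acc = 0;
  // adaptive shrink amplitude: grow on acceptance, cut on rejection, so the
  // protocol takes the largest overlap-free step the configuration admits.
  // Monomeric systems use the exact minimum-gap step instead.
  double amp = 1.0 - shrink_factor;
  bool exact = E.monomeric();
  while (cycles < budget) {
    ++cycles;
    for (long long s = 0; s < relax; ++s) E.one_step();
    double f_needed = std::cbrt(E.phi() / phi_target) * (1.0 - 5e-13);
    ++shrink_att;
    if (exact) {
      if (E.shrink_exact(f_needed)) ++shrink_acc;
    } else {
      double f = std::max(1.0 - amp, f_needed);
      if (E.try_shrink(f)) {
        ++shrink_acc;
        amp = std::min(amp * 1.25, 0.05);
      } else {
        amp = std::max(amp * 0.7, 1e-7);
      }
    }
    if (E.phi() >= phi_target - 1e-12) { reached = true; break; }
    if (cycles % 200 == 0) Rcpp::checkUserInterrupt();
  }
  List out = E.snapshot();
  out["phi"] = E.phi();
  out["reached"] = reached;
  out["cycles"] = (double)cycles;
  out["shrink_attempted"] = (double)shrink_att;
  out["shrink_accepted"] = (double)shrink_acc;
  out["stats"] = E.stats();
  return out;
}

// Tangent random-walk growth of dilute chains with overlap rejection.
// [[Rcpp::export]]
List grow_chains_cpp(IntegerVector lengths, NumericVector L, double sigma,
                     double tol, int seed, int max_site_retry = 60,
                     int max_chain_retry = 400) {
  PBox box(L);
  std::mt19937_64 rng((unsigned long long)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  double bond_len = sigma + 0.5 * tol;
  double h2 = hard_core2(sigma);
  int n = 0;
  for (int l : lengths) n += l;
  arma::mat pos(n, 3);
  CellList cl;
  cl.init(box, n, sigma + tol + 1e-9);
  std::vector<int> placed;  // committed sites

  auto free_pos = [&](const vec3& p) {
    bool ok = true;
    cl.visit(p, [&](int j) {
      if (!ok) return;
      if (box.dist2(p, get_row(pos, j)) < h2) ok = false;
    });
    return ok;
  };

  int base = 0;
  for (int c = 0; c < lengths.size(); ++c) {
    int len = lengths[c];
    bool done = false;
    for (int attempt = 0; attempt < max_chain_retry && !done; ++attempt) {
      std::vector<vec3> walk;
      vec3 head;
      for (int k = 0; k < 3; ++k) head[k] = U(rng) * box.L[k];
      if (!free_pos(head)) continue;
      walk.push_back(head);
      bool fail = false;
      for (int s = 1; s < len; ++s) {
        bool got = false;
        for (int t = 0; t < max_site_retry; ++t) {
          vec3 p = box.wrap(walk.back() + bond_len * rand_unit(rng));
          bool ok = free_pos(p);
          if (ok) {  // also check against the partial walk (not yet in cl)
            for (size_t w = 0; w + 1 < walk.size() && ok; ++w)
              if (box.dist2(p, walk[w]) < h2) ok = false;
          }
          if (ok) { walk.push_back(p); got = true; break; }
        }
        if (!got) { fail = true; break; }
      }
      if (fail) continue;
      for (int s = 0; s < len; ++s) {
        int id = base + s;
        for (int k = 0; k < 3; ++k) pos(id, k) = walk[s][k];
        cl.insert(id, walk[s]);
      }
      done = true;
    }
    if (!done)
      return List::create(_["success"] = false, _["failed_chain"] = c + 1);
    base += len;
  }
  return List::create(_["success"] = true, _["pos"] = pos);
}
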