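// Periodic Voronoi tessellation by sequential half-space clipping.
// Each site's cell starts from the Wigner-Seitz cube of its own periodic
// images and is cut by the perpendicular bisector plane of every nearby
// image, nearest first, until no remaining image can reach the cell
// (candidate distance > twice the farthest vertex).
#include "pack_common.h"
using namespace Rcpp;

namespace {

struct Poly {
  std::vector<vec3> V;
  std::vector<std::vector<int>> F;  // ordered vertex loops, CCW seen from outside
  std::vector<int> nbr;             // generator site of each face (0-based)
};

Poly start_cube(const PBox& box, int self) {
  Poly P;
  double hx = 0.5 * box.L[0], hy = 0.5 * box.L[1], hz = 0.5 * box.L[2];
  for (int iz = 0; iz < 2; ++iz)
    for (int iy = 0; iy < 2; ++iy)
      for (int ix = 0; ix < 2; ++ix) {
        vec3 v;
        v[0] = ix ? hx : -hx; v[1] = iy ? hy : -hy; v[2] = iz ? hz : -hz;
        P.V.push_back(v);
      }
  // vertex index = ix + 2*iy + 4*iz; faces CCW viewed from outside
  P.F = {{1, 3, 7, 5},   // +x
         {0, 4, 6, 2},   // -x
         {2, 6, 7, 3},   // +y
         {0, 1, 5, 4},   // -y
         {4, 5, 7, 6},   // +z
         {0, 2, 3, 1}};  // -z
  P.nbr.assign(6, self);
  return P;
}

// Clip P by half-space dot(nh, x) <= d.  Returns true if the polyhedron changed.
bool clip(Poly& P, const vec3& nh, double d, int nbr_id, double eps) {
  int nv = (int)P.V.size();
  std::vector<double> s(nv);
  bool any_out = false;
  for (int i = 0; i < nv; ++i) {
    s[i] = arma::dot(nh, P.V[i]) - d;
    if (s[i] > eps) any_out = true;
  }
  if (!any_out) return false;

  std::vector<vec3> newV;
  std::vector<int> map_old(nv, -1);
  for (int i = 0; i < nv; ++i)
    if (s[i] <= eps) { map_old[i] = (int)newV.size(); newV.push_back(P.V[i]); }
  if (newV.empty()) return false;  // degenerate; refuse to annihilate the cell

  std::map<std::pair<int,int>, int> edge_cut;  // old edge -> new vertex index
  auto cut_edge = [&](int a, int b) {
    auto key = std::make_pair(std::min(a, b), std::max(a, b));
    auto it = edge_cut.find(key);
    if (it != edge_cut.end()) return it->second;
    double t = s[a] / (s[a] - s[b]);
    vec3 p = P.V[a] + t * (P.V[b] - P.V[a]);
    int idx = (int)newV.size();
    newV.push_back(p);
    edge_cut[key] = idx;
    return idx;
  };

  std::vector<std::vector<int>> newF;
  std::vector<int> newNbr;
  std::vector<int> plane_pts;  // new-vertex indices lying on the cut plane
  auto add_plane_pt = [&](int idx) {
    for (int q : plane_pts) if (q == idx) return;
    plane_pts.push_back(idx);
  };

  for (size_t f = 0; f < P.F.size(); ++f) {
    const std::vector<int>& loop = P.F[f];
    std::vector<int> out;
    int m = (int)loop.size();
    for (int e = 0; e < m; ++e) {
      int a = loop[e], b = loop[(e + 1) % m];
      bool a_in = s[a] < -eps, a_on = std::fabs(s[a]) <= eps;
      bool b_in = s[b] < -eps, b_on = std::fabs(s[b]) <= eps;
      if (a_in || a_on) {
        out.push_back(map_old[a]);
        if (a_on) add_plane_pt(map_old[a]);
      }
      if ((a_in && !b_in && !b_on) || (!a_in && !a_on && b_in)) {
        int idx = cut_edge(a, b);
        out.push_back(idx);
        add_plane_pt(idx);
      }
    }
    if ((int)out.size() >= 3) {
      newF.push_back(out);
      newNbr.push_back(P.nbr[f]);
    }
  }

  // assemble the new face on the cut plane, ordered CCW about nh
  if ((int)plane_pts.size() >= 3) {
    vec3 c = arma::zeros<arma::vec>(3);
    for (int idx : plane_pts) c += newV[idx];
    c /= (double)plane_pts.size();
    // in-plane basis
    vec3 e1 = arma::zeros<arma::vec>(3);
    int kmin = (std::fabs(nh[0]) <= std::fabs(nh[1]) && std::fabs(nh[0]) <= std::fabs(nh[2])) ? 0
             : (std::fabs(nh[1]) <= std::fabs(nh[2]) ? 1 : 2);
    e1[kmin] = 1.0;
    e1 = e1 - nh * arma::dot(nh, e1);
    e1 /= arma::norm(e1);
    vec3 e2 = arma::cross(nh, e1);
    std::vector<std::pair<double,int>> ang;
    for (int idx : plane_pts) {
      vec3 r = newV[idx] - c;
      ang.push_back({std::atan2(arma::dot(r, e2), arma::dot(r, e1)), idx});
    }
    std::sort(ang.begin(), ang.end());
    std::vector<int> loop;
    for (auto& a : ang) loop.push_back(a.second);
    newF.push_back(loop);
    newNbr.push_back(nbr_id);
  }

  // drop unreferenced vertices
  std::vector<int> used((int)newV.size(), 0);
  for (auto& f : newF) for (int v : f) used[v] = 1;
  std::vector<int> remap((int)newV.size(), -1);
  std::vector<vec3> finalV;
  for (size_t i = 0; i < newV.size(); ++i)
    if (used[i]) { remap[i] = (int)finalV.size(); finalV.push_back(newV[i]); }
  for (auto& f : newF) for (int& v : f) v = remap[v];

  P.V = std::move(finalV);
  P.F = std::move(newF);
  P.nbr = std::move(newNbr);
  return true;
}

double poly_volume(const Poly& P) {
  double vol = 0.0;
  for (size_t f = 0; f < P.F.size(); ++f) {
    const std::vector<int>& loop = P.F[f];
    for (size_t t = 1; t + 1 < loop.size(); ++t) {
      vol += arma::dot(P.V[loop[0]],
                       arma::cross(P.V[loop[t]], P.V[loop[t + 1]])) / 6.0;
    }
  }
  return vol;
}

struct Cand { double d2; vec3 q; int id; };

}  // namespace

// [[Rcpp::export]]
List voronoi_cpp(const arma::mat& pos, NumericVector L, double rc_init) {
  PBox box(L);
  int n = pos.n_rows;
  double Lmin = std::min({box.L[0], box.L[1], box.L[2]});
  double Lmax = std::max({box.L[0], box.L[1], box.L[2]});
  double eps = 1e-9 * Lmax;

  double rho = n / box.volume();
  double rc0 = rc_init > 0 ? rc_init
                           : std::min(0.75 * Lmin, std::max(2.5, 3.0 / std::cbrt(rho)));

  List out(n);
  for (int i = 0; i < n; ++i) {
    vec3 pi = get_row(pos, i);
    double rc = rc0;
    Poly P;
    for (int attempt = 0; ; ++attempt) {
      P = start_cube(box, i);
      double Rmax2 = 0.0;
      for (auto& v : P.V) Rmax2 = std::max(Rmax2, arma::dot(v, v));

      // gather images within rc
      std::vector<Cand> cand;
      int sx = (int)std::ceil(rc / box.L[0]);
      int sy = (int)std::ceil(rc / box.L[1]);
      int sz = (int)std::ceil(rc / box.L[2]);
      for (int j = 0; j < n; ++j) {
        vec3 base = get_row(pos, j) - pi;
        for (int ix = -sx; ix <= sx; ++ix)
          for (int iy = -sy; iy <= sy; ++iy)
            for (int iz = -sz; iz <= sz; ++iz) {
              vec3 q = base;
              q[0] += ix * box.L[0]; q[1] += iy * box.L[1]; q[2] += iz * box.L[2];
              double d2 = arma::dot(q, q);
              if (d2 < 1e-20 || d2 > rc * rc) continue;
              cand.push_back({d2, q, j});
            }
      }
      std::sort(cand.begin(), cand.end(),
                [](const Cand& a, const Cand& b) { return a.d2 < b.d2; });

      bool complete = false;
      for (size_t k = 0; k < cand.size(); ++k) {
        if (cand[k].d2 > 4.0 * Rmax2) { complete = true; break; }
        double dlen = std::sqrt(cand[k].d2);
        vec3 nh = cand[k].q / dlen;
        if (clip(P, nh, 0.5 * dlen, cand[k].id, eps)) {
          Rmax2 = 0.0;
          for (auto& v : P.V) Rmax2 = std::max(Rmax2, arma::dot(v, v));
        }
      }
      if (!complete && !cand.empty() && cand.back().d2 <= 4.0 * Rmax2 && attempt < 6) {
        rc *= 1.8;  // cell may extend past the candidate shell: widen and retry
        continue;
      }
      break;
    }

    arma::mat V(P.V.size(), 3);
    for (size_t v = 0; v < P.V.size(); ++v)
      for (int k = 0; k < 3; ++k) V(v, k) = P.V[v][k];
    List faces(P.F.size());
    IntegerVector nbr(P.F.size());
    for (size_t f = 0; f < P.F.size(); ++f) {
      IntegerVector loop(P.F[f].size());
      for (size_t v = 0; v < P.F[f].size(); ++v) loop[v] = P.F[f][v] + 1;
      faces[f] = loop;
      nbr[f] = P.nbr[f] + 1;
    }
    out[i] = List::create(_["site_id"] = i + 1, _["vertices"] = V,
                          _["faces"] = faces, _["neighbor_ids"] = nbr,
                          _["volume"] = poly_volume(P));
  }
  return out;
}
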