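// Core numerical kernels for the Vectorizable Random Lattice (VRL) solver.
//
// The mesh is Voronoi-first: every node's cell is computed by half-plane
// clipping of the domain rectangle against perpendicular bisectors of
// candidate neighbors taken from a window of reference-lattice cells.
// Correctness of the windowed computation is certified by the bound
//   R_max <= k*h/2,
// where R_max is the distance from the node to its farthest cell vertex and
// k the window half-width in cells: every excluded node is at Euclidean
// distance >= k*h, so its bisector cannot cut the computed cell.  When the
// bound fails the window is enlarged, falling back to an all-pairs clip.
// Cocircular node sets (including the exact rectangular limit) need no
// special handling: degenerate faces come out with length ~0 and are
// dropped by the face-length filter.

#include <Rcpp.h>
#include <functional>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Poly {
  // vertex t is (x[t], y[t]); tag[t] labels the edge from vertex t to t+1:
  // -2 clip rectangle, >=0 index of the neighbor whose bisector created it.
  std::vector<double> x, y;
  std::vector<int> tag;
  size_t size() const { return x.size(); }
};

// Clip convex polygon by half-plane {p : (p - m).dir <= 0}. Boundary kept.
void clip_halfplane(Poly& P, double mx, double my, double dx, double dy,
                    int newtag, Poly& out) {
  out.x.clear(); out.y.clear(); out.tag.clear();
  const size_t n = P.size();
  if (n == 0) return;
  std::vector<double> g(n);
  for (size_t t = 0; t < n; ++t)
    g[t] = (P.x[t] - mx) * dx + (P.y[t] - my) * dy;
  for (size_t t = 0; t < n; ++t) {
    size_t u = (t + 1 == n) ? 0 : t + 1;
    bool ain = g[t] <= 0.0, bin = g[u] <= 0.0;
    if (ain) {
      out.x.push_back(P.x[t]); out.y.push_back(P.y[t]);
      out.tag.push_back(P.tag[t]);
      if (!bin) {
        double s = g[t] / (g[t] - g[u]);
        out.x.push_back(P.x[t] + s * (P.x[u] - P.x[t]));
        out.y.push_back(P.y[t] + s * (P.y[u] - P.y[t]));
        out.tag.push_back(newtag); // exit point: continue along the bisector
      }
    } else if (bin) {
      double s = g[t] / (g[t] - g[u]);
      out.x.push_back(P.x[t] + s * (P.x[u] - P.x[t]));
      out.y.push_back(P.y[t] + s * (P.y[u] - P.y[t]));
      out.tag.push_back(P.tag[t]); // entry point: remainder of original edge
    }
  }
}

double poly_area(const Poly& P) {
  double s = 0.0;
  const size_t n = P.size();
  for (size_t t = 0; t < n; ++t) {
    size_t u = (t + 1 == n) ? 0 : t + 1;
    s += P.x[t] * P.y[u] - P.x[u] * P.y[t];
  }
  return 0.5 * std::fabs(s);
}

} // namespace

// Compute clipped Voronoi cells and natural-neighbor faces for a VRL node
// set.  nodes: n x 2; ci, cj: 1-based reference-cell indices (row-major ids
// expected: id = (cj-1)*nx + ci) or zero-length for the unstructured
// all-pairs mode; rect = (x0, y0, x1, y1); window0: initial window
// half-width in cells.  Returns per-node areas/flags and the undirected
// edge table with face lengths f and node distances l.
// [[Rcpp::export]]
List vrl_geometry_cpp(NumericMatrix nodes, IntegerVector ci, IntegerVector cj,
                      int nx, int ny, NumericVector rect, double h,
                      int window0, double f_tol) {
  const int n = nodes.nrow();
  const bool structured = (ci.size() == n) && (n == nx * ny) && n > 1;
  const double x0 = rect[0], y0 = rect[1], x1 = rect[2], y1 = rect[3];

  NumericVector A(n), maxR(n);
  LogicalVector boundary(n);
  // f from each side of every edge, keyed by (min,max)
  std::unordered_map<long long, std::pair<double, double> > faces;
  faces.reserve(6 * n);

  Poly P, Q;
  std::vector<int> cand;
  std::vector<double> d2;
  std::vector<size_t> ord;

  for (int i = 0; i < n; ++i) {
    const double xi = nodes(i, 0), yi = nodes(i, 1);
    int k = structured ? window0 : 0; // k = 0 means all-pairs
    bool ok = false;
    std::vector<double> flen;  // per-candidate face length
    double frect = 0.0;

    while (!ok) {
      cand.clear();
      if (structured && k > 0) {
        const int c0 = ci[i], r0 = cj[i];
        for (int dr = -k; dr <= k; ++dr) {
          int r = r0 + dr;
          if (r < 1 || r > ny) continue;
          for (int dc = -k; dc <= k; ++dc) {
            int c = c0 + dc;
            if (c < 1 || c > nx || (dr == 0 && dc == 0)) continue;
            cand.push_back((r - 1) * nx + (c - 1));
          }
        }
      } else {
        for (int j = 0; j < n; ++j) if (j != i) cand.push_back(j);
      }
      // nearest-first keeps intermediate polygons small
      d2.resize(cand.size());
      ord.resize(cand.size());
      for (size_t t = 0; t < cand.size(); ++t) {
        double dx = nodes(cand[t], 0) - xi, dy = nodes(cand[t], 1) - yi;
        d2[t] = dx * dx + dy * dy;
        ord[t] = t;
      }
      std::sort(ord.begin(), ord.end(),
                [&](size_t a, size_t b) { return d2[a] < d2[b]; });

      // initial polygon: the clip rectangle, counter-clockwise
      P.x = {x0, x1, x1, x0};
      P.y = {y0, y0, y1, y1};
      P.tag = {-2, -2, -2, -2};
      for (size_t t = 0; t < cand.size(); ++t) {
        int j = cand[ord[t]];
        if (d2[ord[t]] <= 0.0)
          stop("coincident nodes encountered while building Voronoi cells");
        double dx = nodes(j, 0) - xi, dy = nodes(j, 1) - yi;
        double mx = 0.5 * (xi + nodes(j, 0)), my = 0.5 * (yi + nodes(j, 1));
        clip_halfplane(P, mx, my, dx, dy, (int)t, Q);
        std::swap(P, Q);
        if (P.size() < 3) stop("zero-area Voronoi cell (node %d)", i + 1);
      }

      double R2 = 0.0;
      for (size_t t = 0; t < P.size(); ++t) {
        double dx = P.x[t] - xi, dy = P.y[t] - yi;
        R2 = std::max(R2, dx * dx + dy * dy);
      }
      maxR[i] = std::sqrt(R2);
      if (structured && k > 0) {
        double bound = 0.5 * k * h;
        if (maxR[i] <= bound * (1.0 - 1e-12)) ok = true;
        else if (2 * k >= std::max(nx, ny)) k = 0; // fall back to all-pairs
        else k *= 2;
      } else {
        ok = true; // all-pairs is always exact
      }
      if (ok) {
        flen.assign(cand.size(), 0.0);
        frect = 0.0;
        for (size_t t = 0; t < P.size(); ++t) {
          size_t u = (t + 1 == P.size()) ? 0 : t + 1;
          double dx = P.x[u] - P.x[t], dy = P.y[u] - P.y[t];
          double len = std::sqrt(dx * dx + dy * dy);
          if (P.tag[t] == -2) frect += len;
          else flen[(size_t)P.tag[t]] += len;
        }
        A[i] = poly_area(P);
        boundary[i] = frect > f_tol;
        for (size_t t = 0; t < cand.size(); ++t) {
          if (flen[t] <= 0.0) continue;
          int j = cand[ord[t]]; // tag t refers to the t-th clip (sorted order)
          long long key = (i < j) ? ((long long)i * n + j)
                                  : ((long long)j * n + i);
          auto it = faces.find(key);
          if (it == faces.end())
            faces[key] = (i < j) ? std::make_pair(flen[t], -1.0)
                                 : std::make_pair(-1.0, flen[t]);
          else {
            if (i < j) it->second.first = flen[t];
            else it->second.second = flen[t];
          }
        }
      }
    }
  }

  // assemble symmetric edge table
  std::vector<int> ei, ej;
  std::vector<double> ef, el;
  double max_asym = 0.0;
  ei.reserve(faces.size()); ej.reserve(faces.size());
  for (auto& kv : faces) {
    int i = (int)(kv.first / n), j = (int)(kv.first % n);
    double fa = kv.second.first, fb = kv.second.second;
    double f;
    if (fa >= 0.0 && fb >= 0.0) {
      f = 0.5 * (fa + fb);
      max_asym = std::max(max_asym, std::fabs(fa - fb));
    } else {
      f = std::max(fa, fb); // seen from one side only (sliver): keep if long
      max_asym = std::max(max_asym, f);
    }
    if (f <= f_tol) continue;
    double dx = nodes(j, 0) - nodes(i, 0), dy = nodes(j, 1) - nodes(i, 1);
    ei.push_back(i + 1); ej.push_back(j + 1);
    ef.push_back(f); el.push_back(std::sqrt(dx * dx + dy * dy));
  }

  return List::create(_["A"] = A, _["boundary"] = boundary, _["maxR"] = maxR,
                      _["i"] = wrap(ei), _["j"] = wrap(ej),
                      _["f"] = wrap(ef), _["l"] = wrap(el),
                      _["max_face_asymmetry"] = max_asym);
}

// Gauss-Seidel split iteration for the Crank-Nicolson step with k = 1
// (component form of the implicit relation):
//   phi_i (1 + c Z_ii phi_i) = rhs_i + c sum_j w_ij phi_j^2,  c = D dt / 4,
//   rhs_i = phin_i + c sum_j w_ij (phin_j^2 - phin_i^2).
// The nonlinear coefficient in the denominator is frozen at the previous
// iterate; neighbor values use the latest sweep values; V^(0) = Phi^n.
// CSR adjacency: ptr (n+1, 0-based), adj (0-based), wadj = w_ij row-wise.
// [[Rcpp::export]]
List gs_cn_k1_cpp(IntegerVector ptr, IntegerVector adj, NumericVector wadj,
                  NumericVector phin, double c, double tol, int maxit) {
  const int n = phin.size();
  std::vector<double> z(n, 0.0), rhs(n), phi(phin.begin(), phin.end());
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int t = ptr[i]; t < ptr[i + 1]; ++t) {
      z[i] += wadj[t];
      s += wadj[t] * (phin[adj[t]] * phin[adj[t]] - phin[i] * phin[i]);
    }
    rhs[i] = phin[i] + c * s;
  }
  int it = 0;
  double delta = R_PosInf;
  while (it < maxit) {
    ++it;
    delta = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int t = ptr[i]; t < ptr[i + 1]; ++t)
        s += wadj[t] * phi[adj[t]] * phi[adj[t]];
      double prev = phi[i];
      phi[i] = (rhs[i] + c * s) / (1.0 + c * z[i] * prev);
      delta = std::max(delta, std::fabs(phi[i] - prev));
    }
    if (delta < tol) break;
  }
  return List::create(_["phi"] = wrap(phi), _["iterations"] = it,
                      _["delta"] = delta, _["converged"] = delta < tol);
}

// One explicit (forward-Euler) step of the full multi-species model on the
// VRL.  Directed weights wij = f/(l*A_i), wji = f/(l*A_j) per undirected
// edge; D1v/beta1v/kv are per-node (global phase = constant vectors).
// X_ may be NULL (two-species model); the three-species growth enhancement
// (1 + rX X) applies to both bacterial reproduction terms.
// [[Rcpp::export]]
List fe_model_step_cpp(IntegerVector ei, IntegerVector ej,
                       NumericVector wij, NumericVector wji, NumericVector A,
                       NumericVector b1, NumericVector b2, NumericVector nf,
                       NumericVector af, Nullable<NumericVector> X_,
                       NumericVector D1v, NumericVector beta1v,
                       NumericVector kv,
                       double D2, double C2, double Dn, double Da,
                       double beta2, double lambda1, double lambda2,
                       double p, double rX, double DX, double CX,
                       double betaX, double muX, double lambdaX,
                       bool algae_literal, double dt) {
  const int n = b1.size(), m = ei.size();
  const bool hasX = X_.isNotNull();
  NumericVector X = hasX ? NumericVector(X_) : NumericVector(0);

  std::vector<double> db1(n, 0.0), db2(n, 0.0), dn(n, 0.0), da(n, 0.0),
      dX(n, 0.0), psi1(n);
  for (int i = 0; i < n; ++i)
    psi1[i] = D1v[i] * (kv[i] == 0.0 ? 1.0 : std::pow(b1[i], kv[i]));

  for (int e = 0; e < m; ++e) {
    const int i = ei[e] - 1, j = ej[e] - 1;
    // P. vortex: nonlinear diffusion grad.[D1 b1^k grad b1]
    double g1 = 0.5 * (psi1[i] + psi1[j]) * (b1[j] - b1[i]);
    db1[i] += wij[e] * g1; db1[j] -= wji[e] * g1;
    // E. coli: self-diffusion + advection along grad b1
    double g2 = D2 * (b2[j] - b2[i])
              + 0.5 * C2 * (b2[i] + b2[j]) * (b1[j] - b1[i]);
    db2[i] += wij[e] * g2; db2[j] -= wji[e] * g2;
    // nutrient, antibiotic: linear diffusion
    double gn = Dn * (nf[j] - nf[i]);
    dn[i] += wij[e] * gn; dn[j] -= wji[e] * gn;
    double ga = Da * (af[j] - af[i]);
    da[i] += wij[e] * ga; da[j] -= wji[e] * ga;
    if (hasX) {
      // both algal transport terms carry X (b2 in the literal variant)
      double ci_ = algae_literal ? b2[i] : X[i];
      double cj_ = algae_literal ? b2[j] : X[j];
      double gX = DX * (cj_ - ci_)
                + 0.5 * CX * (ci_ + cj_) * (b1[j] - b1[i]);
      dX[i] += wij[e] * gX; dX[j] -= wji[e] * gX;
    }
  }

  NumericVector mu1(n), mu2(n), nb1(n), nb2(n), nn(n), na(n),
      nX(hasX ? n : 0);
  double clip1 = 0.0, clip2 = 0.0, clipn = 0.0, clipa = 0.0, clipX = 0.0;
  for (int i = 0; i < n; ++i) {
    mu1[i] = 0.3 * af[i] / (1.0 + 4.0 * nf[i]);
    mu2[i] = 1.0 / (1.0 + 4.0 * nf[i]);
    double G = hasX ? (1.0 + rX * X[i]) : 1.0;
    db1[i] += (beta1v[i] * nf[i] * G - mu1[i]) * b1[i];
    db2[i] += (beta2 * nf[i] * G - mu2[i]) * b2[i];
    dn[i] -= nf[i] * (lambda1 * b1[i] + lambda2 * b2[i]
                      + (hasX ? lambdaX * X[i] : 0.0));
    da[i] -= p * af[i] * b2[i];
    if (hasX) dX[i] += (betaX * nf[i] - muX) * X[i];

    double v;
    v = b1[i] + dt * db1[i];
    if (v < 0) { clip1 -= v * A[i]; v = 0; } nb1[i] = v;
    v = b2[i] + dt * db2[i];
    if (v < 0) { clip2 -= v * A[i]; v = 0; } nb2[i] = v;
    v = nf[i] + dt * dn[i];
    if (v < 0) { clipn -= v * A[i]; v = 0; } nn[i] = v;
    v = af[i] + dt * da[i];
    if (v < 0) { clipa -= v * A[i]; v = 0; } na[i] = v;
    if (hasX) {
      v = X[i] + dt * dX[i];
      if (v < 0) { clipX -= v * A[i]; v = 0; } nX[i] = v;
    }
    if (!std::isfinite(nb1[i]) || !std::isfinite(nb2[i]) ||
        !std::isfinite(nn[i]) || !std::isfinite(na[i]))
      stop("non-finite field value at node %d: time step too large "
           "for explicit integration on this mesh", i + 1);
  }

  List out = List::create(_["b1"] = nb1, _["b2"] = nb2, _["n"] = nn,
                          _["a"] = na, _["mu1"] = mu1, _["mu2"] = mu2,
                          _["clipped"] = NumericVector::create(
                              clip1, clip2, clipn, clipa, clipX));
  if (hasX) out["X"] = nX;
  return out;
}

namespace {

int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
  return x;
}

} // namespace

// Full explicit integration loop for the multi-species colony model: the
// per-step physics of fe_model_step_cpp plus dead-mass accumulation and the
// hysteretic builder/explorer phase switch (global, or per connected
// component of the colony support when multi_colony is true; a merged
// component adopts the phase holding the majority of its mass).  Phase is
// re-evaluated after every step.  Diagnostics are recorded every
// record_every steps; full field snapshots at the 1-based steps in
// snap_steps.  phase codes: 0 builder, 1 explorer, 2 mixed (per-component
// mode only).
// [[Rcpp::export]]
List run_core_cpp(IntegerVector ei, IntegerVector ej,
                  NumericVector wij, NumericVector wji, NumericVector A,
                  NumericVector x, NumericVector y, NumericVector center,
                  NumericVector b1_0, NumericVector b2_0, NumericVector n_0,
                  NumericVector a_0, Nullable<NumericVector> X_0,
                  bool hasX, List pars, double support_thr, bool rule_sum,
                  double bbar_min, double bbar_max, bool multi_colony,
                  double dt, int nsteps, int record_every,
                  IntegerVector snap_steps, double radius_prob,
                  double t0) {
  const int n = b1_0.size(), m = ei.size();
  auto P = [&](const char* k) { return as<double>(pars[k]); };
  const double D1b = P("D1_build"), D1e = P("D1_explore");
  const double be1b = P("beta1_build"), be1e = P("beta1_explore");
  const double kb = P("k_build"), ke = P("k_explore");
  const double D2 = P("D2"), C2 = P("C2"), Dn = P("Dn"), Da = P("Da");
  const double beta2 = P("beta2"), l1 = P("lambda1"), l2 = P("lambda2");
  const double pdeg = P("p"), rX = P("rX"), DX = P("DX"), CX = P("CX");
  const double betaX = P("betaX"), muX = P("muX"), lX = P("lambdaX");
  const bool algae_literal = as<bool>(pars["algae_diffusion_literal"]);

  std::vector<double> b1(b1_0.begin(), b1_0.end()),
      b2(b2_0.begin(), b2_0.end()), nf(n_0.begin(), n_0.end()),
      af(a_0.begin(), a_0.end()), X, s1(n, 0.0), s2(n, 0.0), sX,
      db1(n), db2(n), dn(n), da(n), dX, psi1(n), dist(n);
  if (hasX) {
    NumericVector xv(X_0);
    X.assign(xv.begin(), xv.end());
    sX.assign(n, 0.0); dX.assign(n, 0.0);
  }
  for (int i = 0; i < n; ++i) {
    double ddx = x[i] - center[0], ddy = y[i] - center[1];
    dist[i] = std::sqrt(ddx * ddx + ddy * ddy);
  }

  // phase state: global scalar or per node
  int phase_g = 0;                 // builders initially
  std::vector<int> phase_node(n, 0);
  int switches = 0;
  double clipped = 0.0, t = t0;

  const int nrec = nsteps / record_every + 1;
  NumericVector rec_t(nrec), rec_radius(nrec), rec_bbar(nrec),
      rec_m1(nrec), rec_m2(nrec), rec_ma(nrec);
  IntegerVector rec_phase(nrec), rec_ncomp(nrec);
  int irec = 0;

  std::vector<int> parent(n), comp_of(n);
  std::vector<double> sel(n), rbuf;

  auto bbar_of = [&](double& bbar_out) {
    double ms = 0.0, as_ = 0.0;
    for (int i = 0; i < n; ++i) {
      sel[i] = rule_sum ? b1[i] + b2[i] : b1[i];
      if (sel[i] > support_thr) { ms += A[i] * sel[i]; as_ += A[i]; }
    }
    bbar_out = as_ > 0 ? ms / as_ : 0.0;
  };

  int ncomp_cur = 1;
  // apply = false only measures (component count, bbar) without touching
  // the phase state; used for the t = 0 diagnostics record
  auto phase_step = [&](bool apply) {
    double bbar;
    bbar_of(bbar);
    if (!multi_colony) {
      if (!apply) { ncomp_cur = 1; return bbar; }
      int np = phase_g;
      if (phase_g == 0 && bbar > bbar_max) np = 1;
      else if (phase_g == 1 && bbar < bbar_min) np = 0;
      if (np != phase_g) ++switches;
      phase_g = np;
      ncomp_cur = 1;
    } else {
      for (int i = 0; i < n; ++i) parent[i] = i;
      for (int e = 0; e < m; ++e) {
        int i = ei[e] - 1, j = ej[e] - 1;
        if (sel[i] > support_thr && sel[j] > support_thr) {
          int ri = uf_find(parent, i), rj = uf_find(parent, j);
          if (ri != rj) parent[ri] = rj;
        }
      }
      std::unordered_map<int, int> remap;
      int nc = 0;
      for (int i = 0; i < n; ++i) {
        if (sel[i] <= support_thr) { comp_of[i] = -1; continue; }
        int r = uf_find(parent, i);
        auto it = remap.find(r);
        if (it == remap.end()) { remap[r] = nc; comp_of[i] = nc; ++nc; }
        else comp_of[i] = it->second;
      }
      std::vector<double> wtot(nc, 0.0), wexp(nc, 0.0), msum(nc, 0.0),
          asum(nc, 0.0);
      for (int i = 0; i < n; ++i) {
        if (comp_of[i] < 0) continue;
        double w = A[i] * sel[i];
        wtot[comp_of[i]] += w;
        if (phase_node[i] == 1) wexp[comp_of[i]] += w;
        msum[comp_of[i]] += A[i] * sel[i];
        asum[comp_of[i]] += A[i];
      }
      if (!apply) { ncomp_cur = std::max(nc, 1); return bbar; }
      std::vector<int> cphase(nc);
      for (int c = 0; c < nc; ++c) {
        int cur = (wexp[c] > 0.5 * wtot[c]) ? 1 : 0;
        double bb = asum[c] > 0 ? msum[c] / asum[c] : 0.0;
        int np = cur;
        if (cur == 0 && bb > bbar_max) np = 1;
        else if (cur == 1 && bb < bbar_min) np = 0;
        if (np != cur) ++switches;
        cphase[c] = np;
      }
      bool any_b = false, any_e = false;
      for (int i = 0; i < n; ++i) {
        phase_node[i] = comp_of[i] >= 0 ? cphase[comp_of[i]] : 0;
        if (comp_of[i] >= 0) {
          if (phase_node[i] == 1) any_e = true; else any_b = true;
        }
      }
      phase_g = any_e && any_b ? 2 : (any_e ? 1 : 0);
      ncomp_cur = std::max(nc, 1);
    }
    return bbar;
  };

  auto record = [&](double bbar) {
    rec_t[irec] = t;
    double m1 = 0.0, m2 = 0.0, ma = 0.0;
    rbuf.clear();
    for (int i = 0; i < n; ++i) {
      m1 += A[i] * b1[i]; m2 += A[i] * b2[i]; ma += A[i] * af[i];
      if (b1[i] + b2[i] > support_thr) rbuf.push_back(dist[i]);
    }
    double radius = 0.0;
    if (!rbuf.empty()) {
      // type-7 quantile to match R's default
      double hq = (rbuf.size() - 1) * radius_prob;
      size_t lo = (size_t)std::floor(hq);
      size_t hi = std::min(lo + 1, rbuf.size() - 1);
      std::nth_element(rbuf.begin(), rbuf.begin() + lo, rbuf.end());
      double vlo = rbuf[lo];
      std::nth_element(rbuf.begin(), rbuf.begin() + hi, rbuf.end());
      radius = vlo + (hq - lo) * (rbuf[hi] - vlo);
    }
    rec_radius[irec] = radius; rec_bbar[irec] = bbar;
    rec_phase[irec] = phase_g; rec_ncomp[irec] = ncomp_cur;
    rec_m1[irec] = m1; rec_m2[irec] = m2; rec_ma[irec] = ma;
    ++irec;
  };

  record(phase_step(false));

  List snapshots(snap_steps.size());

  for (int step = 1; step <= nsteps; ++step) {
    const bool g_exp = phase_g == 1;
    for (int i = 0; i < n; ++i) {
      double D1, kk;
      if (multi_colony) {
        D1 = phase_node[i] == 1 ? D1e : D1b;
        kk = phase_node[i] == 1 ? ke : kb;
      } else {
        D1 = g_exp ? D1e : D1b;
        kk = g_exp ? ke : kb;
      }
      psi1[i] = D1 * (kk == 0.0 ? 1.0 : std::pow(b1[i], kk));
      db1[i] = db2[i] = dn[i] = da[i] = 0.0;
      if (hasX) dX[i] = 0.0;
    }
    for (int e = 0; e < m; ++e) {
      const int i = ei[e] - 1, j = ej[e] - 1;
      const double grad1 = b1[j] - b1[i];
      double g1 = 0.5 * (psi1[i] + psi1[j]) * grad1;
      db1[i] += wij[e] * g1; db1[j] -= wji[e] * g1;
      double g2 = D2 * (b2[j] - b2[i]) + 0.5 * C2 * (b2[i] + b2[j]) * grad1;
      db2[i] += wij[e] * g2; db2[j] -= wji[e] * g2;
      double gn = Dn * (nf[j] - nf[i]);
      dn[i] += wij[e] * gn; dn[j] -= wji[e] * gn;
      double ga = Da * (af[j] - af[i]);
      da[i] += wij[e] * ga; da[j] -= wji[e] * ga;
      if (hasX) {
        // both algal transport terms carry X (b2 in the literal variant)
        const double ci_ = algae_literal ? b2[i] : X[i];
        const double cj_ = algae_literal ? b2[j] : X[j];
        double gX = DX * (cj_ - ci_) + 0.5 * CX * (ci_ + cj_) * grad1;
        dX[i] += wij[e] * gX; dX[j] -= wji[e] * gX;
      }
    }
    for (int i = 0; i < n; ++i) {
      const double beta1 = multi_colony
        ? (phase_node[i] == 1 ? be1e : be1b) : (g_exp ? be1e : be1b);
      const double mu1 = 0.3 * af[i] / (1.0 + 4.0 * nf[i]);
      const double mu2 = 1.0 / (1.0 + 4.0 * nf[i]);
      const double G = hasX ? (1.0 + rX * X[i]) : 1.0;
      s1[i] += dt * mu1 * b1[i];
      s2[i] += dt * mu2 * b2[i];
      if (hasX) sX[i] += dt * muX * X[i];
      db1[i] += (beta1 * nf[i] * G - mu1) * b1[i];
      db2[i] += (beta2 * nf[i] * G - mu2) * b2[i];
      dn[i] -= nf[i] * (l1 * b1[i] + l2 * b2[i] + (hasX ? lX * X[i] : 0.0));
      da[i] -= pdeg * af[i] * b2[i];
      if (hasX) dX[i] += (betaX * nf[i] - muX) * X[i];

      // clip negatives (explicit reactions) and flush values hundreds of
      // orders below the support threshold to zero: they are physically
      // meaningless and subnormal arithmetic is pathologically slow
      double v;
      v = b1[i] + dt * db1[i];
      if (v < 0) { clipped -= v * A[i]; v = 0; }
      b1[i] = v < 1e-280 ? 0.0 : v;
      v = b2[i] + dt * db2[i];
      if (v < 0) { clipped -= v * A[i]; v = 0; }
      b2[i] = v < 1e-280 ? 0.0 : v;
      v = nf[i] + dt * dn[i];
      if (v < 0) { clipped -= v * A[i]; v = 0; }
      nf[i] = v < 1e-280 ? 0.0 : v;
      v = af[i] + dt * da[i];
      if (v < 0) { clipped -= v * A[i]; v = 0; }
      af[i] = v < 1e-280 ? 0.0 : v;
      if (hasX) {
        v = X[i] + dt * dX[i];
        if (v < 0) { clipped -= v * A[i]; v = 0; }
        X[i] = v < 1e-280 ? 0.0 : v;
      }
      if (!std::isfinite(b1[i]) || !std::isfinite(nf[i]))
        stop("non-finite field at node %d, step %d: dt too large for "
             "explicit integration on this mesh", i + 1, step);
    }
    t = t0 + step * dt;
    double bbar = phase_step(true);
    if (step % record_every == 0 && irec < nrec) record(bbar);
    for (int s = 0; s < snap_steps.size(); ++s) {
      if (snap_steps[s] == step) {
        List snap = List::create(
          _["t"] = t, _["b1"] = wrap(b1), _["b2"] = wrap(b2),
          _["n"] = wrap(nf), _["a"] = wrap(af),
          _["s1"] = wrap(s1), _["s2"] = wrap(s2));
        if (hasX) { snap["X"] = wrap(X); snap["sX"] = wrap(sX); }
        snapshots[s] = snap;
      }
    }
  }

  return List::create(
    _["series"] = List::create(
      _["t"] = rec_t, _["radius"] = rec_radius, _["bbar"] = rec_bbar,
      _["phase"] = rec_phase, _["ncomp"] = rec_ncomp,
      _["mass_b1"] = rec_m1, _["mass_b2"] = rec_m2, _["mass_a"] = rec_ma),
    _["nrec"] = irec,
    _["final"] = List::create(
      _["b1"] = wrap(b1), _["b2"] = wrap(b2), _["n"] = wrap(nf),
      _["a"] = wrap(af), _["s1"] = wrap(s1), _["s2"] = wrap(s2),
      _["X"] = hasX ? wrap(X) : R_NilValue,
      _["sX"] = hasX ? wrap(sX) : R_NilValue),
    _["snapshots"] = snapshots, _["switches"] = switches,
    _["clipped"] = clipped, _["phase"] = phase_g);
}

// Connected components of the natural-neighbor graph restricted to active
// nodes.  Returns 0 for inactive nodes, 1..k component labels otherwise.
// [[Rcpp::export]]
IntegerVector components_cpp(int n, IntegerVector ei, IntegerVector ej,
                             LogicalVector active) {
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  const int m = ei.size();
  for (int e = 0; e < m; ++e) {
    int i = ei[e] - 1, j = ej[e] - 1;
    if (active[i] && active[j]) {
      int ri = find(i), rj = find(j);
      if (ri != rj) parent[ri] = rj;
    }
  }
  IntegerVector lab(n, 0);
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!active[i]) continue;
    int r = find(i);
    auto it = remap.find(r);
    if (it == remap.end()) { remap[r] = ++next; lab[i] = next; }
    else lab[i] = it->second;
  }
  return lab;
}
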