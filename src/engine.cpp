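// Stochastic engine: lattice kinetics of McdA, elastic McdA-McdB tethers,
// carboxysome self-association springs, overdamped Brownian dynamics.
//
// Units here: lengths nm, times s, forces pN, energies pN*nm.
// All randomness comes from R's RNG (unif_rand/norm_rand/R::rbinom) so that
// set.seed() on the R side gives fully reproducible trajectories. Draw order
// is fixed: particles are visited by id, bonds by (carboxysome, site) index.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Pars {
  double Lx, Ly, a, diam;
  int nx, ny, nsites;
  double k_off, k_rebind, k_bond_on, k_bond_off;
  double D_A, D_carb, capture, kBT;
  int n_mcdA, n_mcdB, n_carb;
  double k_AB, k_self, rest_AB, rest_self, self_range, max_ext;
  double dt;
  double p_hop, p_rebind, p_unbind, p_on, p_off;
  double mob, noise_sd;
};

static Pars make_pars(const List& p) {
  List g = p["geometry"], k = p["kinetics"], s = p["springs"], r = p["run"];
  Pars P;
  P.Lx = as<double>(g["nucleoid_length"]) * 1000.0;  // um -> nm
  P.Ly = as<double>(g["nucleoid_width"]) * 1000.0;
  P.a = as<double>(g["lattice_spacing"]);
  P.diam = as<double>(g["carboxysome_diameter"]);
  P.nx = (int) std::lround(P.Lx / P.a);
  P.ny = (int) std::lround(P.Ly / P.a);
  P.nsites = P.nx * P.ny;
  P.k_off = as<double>(k["k_off_intrinsic"]);
  P.k_rebind = as<double>(k["k_rebind"]);
  P.k_bond_on = as<double>(k["k_bond_on"]);
  P.k_bond_off = as<double>(k["k_bond_off"]);
  P.D_A = as<double>(k["D_mcdA_nucleoid"]) * 1e6;    // um^2/s -> nm^2/s
  P.D_carb = as<double>(k["D_carb"]) * 1e6;
  P.n_mcdA = as<int>(k["n_mcdA"]);
  P.n_mcdB = as<int>(k["n_mcdB_per_carb"]);
  P.capture = as<double>(k["capture_radius"]);
  P.kBT = as<double>(k["kBT"]);
  P.k_AB = as<double>(s["k_AB"]);
  P.k_self = as<double>(s["k_self"]);
  P.rest_AB = as<double>(s["rest_length_AB"]);
  P.rest_self = as<double>(s["rest_length_self"]);
  P.self_range = as<double>(s["self_range"]);
  P.max_ext = as<double>(s["max_extension_AB"]);
  P.dt = as<double>(r["dt"]);
  P.n_carb = as<int>(r["n_carboxysomes"]);
  P.p_hop = 4.0 * P.D_A / (P.a * P.a) * P.dt;
  P.p_rebind = -std::expm1(-P.k_rebind * P.dt);
  P.p_unbind = -std::expm1(-P.k_off * P.dt);
  P.p_on = -std::expm1(-P.k_bond_on * P.dt);
  P.p_off = -std::expm1(-P.k_bond_off * P.dt);
  P.mob = (P.D_carb > 0.0) ? P.D_carb / P.kBT : 0.0;
  P.noise_sd = std::sqrt(2.0 * P.D_carb * P.dt);
  return P;
}

struct State {
  double time;
  std::vector<double> cx, cy;                 // carboxysome centers
  std::vector<double> offx, offy;             // McdB offsets, c*n_mcdB + j
  std::vector<int> site;                      // per McdA: -1 cytoplasm, else lattice idx
  std::vector<int> occ;                       // per lattice site: -1 or McdA idx
  std::vector<int> site_bond;                 // per McdB site: -1 or McdA idx
  std::vector<int> a_bond_carb, a_bond_site;  // per McdA: -1 or carb / McdB-site idx
};

static State from_list(const List& st, const Pars& P) {
  State S;
  S.time = as<double>(st["time"]);
  NumericMatrix carb = st["carb"];
  if (carb.nrow() != P.n_carb)
    stop("state has %d carboxysomes but params say %d", carb.nrow(), P.n_carb);
  for (int c = 0; c < P.n_carb; ++c) { S.cx.push_back(carb(c, 0)); S.cy.push_back(carb(c, 1)); }
  List offs = st["offsets"];
  S.offx.assign((size_t)P.n_carb * P.n_mcdB, 0.0);
  S.offy.assign((size_t)P.n_carb * P.n_mcdB, 0.0);
  for (int c = 0; c < P.n_carb; ++c) {
    NumericMatrix om = offs[c];
    if (om.nrow() != P.n_mcdB) stop("offsets for carboxysome %d have wrong length", c + 1);
    for (int j = 0; j < P.n_mcdB; ++j) {
      S.offx[(size_t)c * P.n_mcdB + j] = om(j, 0);
      S.offy[(size_t)c * P.n_mcdB + j] = om(j, 1);
    }
  }
  IntegerVector ms = st["mcda_site"], oc = st["occupancy"];
  IntegerVector abc = st["mcda_bond_carb"], abs_ = st["mcda_bond_site"];
  IntegerMatrix bm = st["bond_mcda"];
  if (ms.size() != P.n_mcdA) stop("mcda_site length != n_mcdA");
  if (oc.size() != P.nsites) stop("occupancy length != number of lattice sites");
  S.site.resize(P.n_mcdA); S.a_bond_carb.resize(P.n_mcdA); S.a_bond_site.resize(P.n_mcdA);
  for (int i = 0; i < P.n_mcdA; ++i) {
    S.site[i] = ms[i] - 1;           // R: 0 = cytoplasm
    S.a_bond_carb[i] = abc[i] - 1;
    S.a_bond_site[i] = abs_[i] - 1;
  }
  S.occ.resize(P.nsites);
  for (int s = 0; s < P.nsites; ++s) S.occ[s] = oc[s] - 1;
  S.site_bond.assign((size_t)P.n_carb * P.n_mcdB, -1);
  for (int c = 0; c < P.n_carb; ++c)
    for (int j = 0; j < P.n_mcdB; ++j)
      S.site_bond[(size_t)c * P.n_mcdB + j] = bm(j, c) - 1;
  return S;
}

static List to_list(const State& S, const Pars& P) {
  NumericMatrix carb(P.n_carb, 2);
  for (int c = 0; c < P.n_carb; ++c) { carb(c, 0) = S.cx[c]; carb(c, 1) = S.cy[c]; }
  List offs(P.n_carb);
  for (int c = 0; c < P.n_carb; ++c) {
    NumericMatrix om(P.n_mcdB, 2);
    for (int j = 0; j < P.n_mcdB; ++j) {
      om(j, 0) = S.offx[(size_t)c * P.n_mcdB + j];
      om(j, 1) = S.offy[(size_t)c * P.n_mcdB + j];
    }
    offs[c] = om;
  }
  IntegerVector ms(P.n_mcdA), abc(P.n_mcdA), abs_(P.n_mcdA);
  for (int i = 0; i < P.n_mcdA; ++i) {
    ms[i] = S.site[i] + 1; abc[i] = S.a_bond_carb[i] + 1; abs_[i] = S.a_bond_site[i] + 1;
  }
  IntegerVector oc(P.nsites);
  for (int s = 0; s < P.nsites; ++s) oc[s] = S.occ[s] + 1;
  IntegerMatrix bm(P.n_mcdB, P.n_carb);
  for (int c = 0; c < P.n_carb; ++c)
    for (int j = 0; j < P.n_mcdB; ++j)
      bm(j, c) = S.site_bond[(size_t)c * P.n_mcdB + j] + 1;
  List out = List::create(
    _["time"] = S.time, _["carb"] = carb, _["offsets"] = offs,
    _["mcda_site"] = ms, _["occupancy"] = oc, _["bond_mcda"] = bm,
    _["mcda_bond_carb"] = abc, _["mcda_bond_site"] = abs_);
  out.attr("class") = "mcd_state";
  return out;
}

static inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// Uniformly random k-subset of {0..n-1}, returned sorted so that particles
// are then processed in id order. Equivalent in distribution to independent
// Bernoulli draws per particle when k ~ Binomial(n, p). Epoch-stamped
// scratch avoids a per-step allocation (single-threaded under R's RNG).
static std::vector<int> g_stamp;
static int g_epoch = 0;
static void rand_subset(int n, int k, std::vector<int>& out) {
  out.clear();
  if (k <= 0) return;
  if (k >= n) { for (int i = 0; i < n; ++i) out.push_back(i); return; }
  if ((int)g_stamp.size() < n) g_stamp.resize(n, 0);
  ++g_epoch;
  bool invert = k > n / 2;
  int kk = invert ? n - k : k;
  int got = 0;
  while (got < kk) {
    int c = rand_int(n);
    if (g_stamp[c] != g_epoch) { g_stamp[c] = g_epoch; ++got; }
  }
  for (int i = 0; i < n; ++i)
    if ((g_stamp[i] == g_epoch) != invert) out.push_back(i);
}

static inline double site_x(int s, const Pars& P) { return (s % P.nx + 0.5) * P.a; }
static inline double site_y(int s, const Pars& P) { return (s / P.nx + 0.5) * P.a; }

// Elastic energy of McdA i's bond when anchored at lattice site s.
static double bond_energy_at(const State& S, const Pars& P, int i, int s) {
  int c = S.a_bond_carb[i], j = S.a_bond_site[i];
  int g = c * P.n_mcdB + j;
  double ex = S.cx[c] + S.offx[g] - site_x(s, P);
  double ey = S.cy[c] + S.offy[g] - site_y(s, P);
  double e = std::sqrt(ex * ex + ey * ey);
  double stretch = (P.rest_AB > 0.0) ? (e - P.rest_AB) : e;
  return 0.5 * P.k_AB * stretch * stretch;
}

// (1) lattice hops of nucleoid McdA (hard exclusion, edge-bounded). Unbonded
// particles hop freely; bonded particles (the tether anchors) hop with
// Metropolis acceptance exp(-dE/kBT) on the elastic bond energy, so soft
// tethers relay along the nucleoid while stiff tethers freeze their anchors.
static void do_hop(State& S, const Pars& P) {
  if (P.p_hop <= 0.0) return;
  static std::vector<int> movers;
  movers.clear();
  for (int i = 0; i < P.n_mcdA; ++i)
    if (S.site[i] >= 0) movers.push_back(i);
  if (movers.empty()) return;
  int k = (int) R::rbinom((double)movers.size(), P.p_hop);
  if (k == 0) return;
  static std::vector<int> sel;
  rand_subset((int)movers.size(), k, sel);
  static const int DX[4] = {1, -1, 0, 0};
  static const int DY[4] = {0, 0, 1, -1};
  for (int idx : sel) {
    int i = movers[idx];
    int s = S.site[i];
    int ix = s % P.nx, iy = s / P.nx;
    int d = rand_int(4);
    int jx = ix + DX[d], jy = iy + DY[d];
    if (jx < 0 || jx >= P.nx || jy < 0 || jy >= P.ny) continue;  // hard edge
    int t = jy * P.nx + jx;
    if (S.occ[t] >= 0) continue;                                 // exclusion
    if (S.a_bond_carb[i] >= 0) {
      double dE = bond_energy_at(S, P, i, t) - bond_energy_at(S, P, i, s);
      if (dE > 0.0 && unif_rand() >= std::exp(-dE / P.kBT)) continue;
    }
    S.occ[s] = -1; S.occ[t] = i; S.site[i] = t;
  }
}

// (2) cytoplasm -> nucleoid rebinding to a uniformly random empty site
static void do_rebind(State& S, const Pars& P) {
  if (P.p_rebind <= 0.0) return;
  static std::vector<int> cyto;
  cyto.clear();
  for (int i = 0; i < P.n_mcdA; ++i) if (S.site[i] < 0) cyto.push_back(i);
  if (cyto.empty()) return;
  int k = (int) R::rbinom((double)cyto.size(), P.p_rebind);
  if (k == 0) return;
  static std::vector<int> sel;
  rand_subset((int)cyto.size(), k, sel);
  int n_empty = 0;
  for (int s = 0; s < P.nsites; ++s) if (S.occ[s] < 0) ++n_empty;
  for (int idx : sel) {
    int i = cyto[idx];
    if (n_empty <= 0) continue;  // no capacity: particle stays cytoplasmic
    int s = -1;
    for (int tries = 0; tries < 1000; ++tries) {
      int c = rand_int(P.nsites);
      if (S.occ[c] < 0) { s = c; break; }
    }
    if (s < 0) {  // dense lattice fallback: scan from a random start
      int start = rand_int(P.nsites);
      for (int o = 0; o < P.nsites; ++o) {
        int c = (start + o) % P.nsites;
        if (S.occ[c] < 0) { s = c; break; }
      }
    }
    if (s < 0) continue;
    S.occ[s] = i; S.site[i] = s; --n_empty;
  }
}

// (3) intrinsic dissociation of unbonded nucleoid McdA
static void do_unbind(State& S, const Pars& P) {
  if (P.p_unbind <= 0.0) return;
  static std::vector<int> free_on;
  free_on.clear();
  for (int i = 0; i < P.n_mcdA; ++i)
    if (S.site[i] >= 0 && S.a_bond_carb[i] < 0) free_on.push_back(i);
  if (free_on.empty()) return;
  int k = (int) R::rbinom((double)free_on.size(), P.p_unbind);
  if (k == 0) return;
  static std::vector<int> sel;
  rand_subset((int)free_on.size(), k, sel);
  for (int idx : sel) {
    int i = free_on[idx];
    S.occ[S.site[i]] = -1;
    S.site[i] = -1;
  }
}

struct Cand { double d2; int gsite; int m; int c; int j; };

// (4) bond formation: free McdB sites pair with the nearest free nucleoid
// McdA within the capture radius; conflicts resolved greedily by distance,
// then site index, then McdA id; each matched pair then fires with
// probability 1 - exp(-k_bond_on * dt).
static void do_form_bonds(State& S, const Pars& P) {
  if (P.p_on <= 0.0 || P.n_carb == 0) return;
  static std::vector<Cand> cands;
  cands.clear();
  const double cap2 = P.capture * P.capture;
  // For each carboxysome: bin its free McdB sites into a local grid, then
  // scan lattice cells near the disk for free McdA and test only the sites
  // in neighboring bins. Same candidate set as the all-pairs scan.
  const double reach = P.diam / 2.0 + P.capture;
  const int nb = (int)std::ceil(2.0 * reach / P.a) + 2;  // local bins per axis
  static std::vector<int> bin_head, nxt;
  for (int c = 0; c < P.n_carb; ++c) {
    bin_head.assign((size_t)nb * nb, -1);
    nxt.assign((size_t)P.n_mcdB, -1);
    const double ox = S.cx[c] - reach - P.a, oy = S.cy[c] - reach - P.a;
    bool any_free = false;
    for (int j = 0; j < P.n_mcdB; ++j) {
      int g = c * P.n_mcdB + j;
      if (S.site_bond[g] >= 0) continue;
      any_free = true;
      int bx = (int)std::floor((S.cx[c] + S.offx[g] - ox) / P.a);
      int by = (int)std::floor((S.cy[c] + S.offy[g] - oy) / P.a);
      int b = by * nb + bx;
      nxt[j] = bin_head[b];
      bin_head[b] = j;
    }
    if (!any_free) continue;
    int ix0 = (int)std::floor((S.cx[c] - reach) / P.a);
    int ix1 = (int)std::floor((S.cx[c] + reach) / P.a);
    int iy0 = (int)std::floor((S.cy[c] - reach) / P.a);
    int iy1 = (int)std::floor((S.cy[c] + reach) / P.a);
    if (ix0 < 0) ix0 = 0; if (iy0 < 0) iy0 = 0;
    if (ix1 >= P.nx) ix1 = P.nx - 1; if (iy1 >= P.ny) iy1 = P.ny - 1;
    for (int iy = iy0; iy <= iy1; ++iy) {
      for (int ix = ix0; ix <= ix1; ++ix) {
        int t = iy * P.nx + ix;
        int m = S.occ[t];
        if (m < 0 || S.a_bond_carb[m] >= 0) continue;
        double sx = site_x(t, P), sy = site_y(t, P);
        int bx = (int)std::floor((sx - ox) / P.a);
        int by = (int)std::floor((sy - oy) / P.a);
        int rr = (int)std::ceil(P.capture / P.a);
        for (int dy = -rr; dy <= rr; ++dy) {
          for (int dx = -rr; dx <= rr; ++dx) {
            int jx = bx + dx, jy = by + dy;
            if (jx < 0 || jx >= nb || jy < 0 || jy >= nb) continue;
            for (int j = bin_head[jy * nb + jx]; j >= 0; j = nxt[j]) {
              int g = c * P.n_mcdB + j;
              double px = S.cx[c] + S.offx[g], py = S.cy[c] + S.offy[g];
              double ddx = px - sx, ddy = py - sy;
              double d2 = ddx * ddx + ddy * ddy;
              if (d2 <= cap2) cands.push_back(Cand{d2, g, m, c, j});
            }
          }
        }
      }
    }
  }
  if (cands.empty()) return;
  std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
    if (a.d2 != b.d2) return a.d2 < b.d2;
    if (a.gsite != b.gsite) return a.gsite < b.gsite;
    return a.m < b.m;
  });
  static std::vector<char> site_taken, m_taken;
  site_taken.assign((size_t)P.n_carb * P.n_mcdB, 0);
  m_taken.assign((size_t)P.n_mcdA, 0);
  static std::vector<const Cand*> matched;
  matched.clear();
  for (const Cand& cd : cands) {
    if (site_taken[cd.gsite] || m_taken[cd.m]) continue;
    site_taken[cd.gsite] = 1; m_taken[cd.m] = 1;
    matched.push_back(&cd);
  }
  for (const Cand* cd : matched) {
    if (P.p_on >= 1.0 || unif_rand() < P.p_on) {
      S.site_bond[cd->gsite] = cd->m;
      S.a_bond_carb[cd->m] = cd->c;
      S.a_bond_site[cd->m] = cd->j;
    }
  }
}

// (5a) elastic tether forces on each carboxysome (zero rest length default)
static void calc_bond_forces(const State& S, const Pars& P,
                             std::vector<double>& fx, std::vector<double>& fy) {
  fx.assign(P.n_carb, 0.0); fy.assign(P.n_carb, 0.0);
  for (int c = 0; c < P.n_carb; ++c) {
    for (int j = 0; j < P.n_mcdB; ++j) {
      int g = c * P.n_mcdB + j;
      int m = S.site_bond[g];
      if (m < 0) continue;
      int s = S.site[m];
      double ex = S.cx[c] + S.offx[g] - site_x(s, P);
      double ey = S.cy[c] + S.offy[g] - site_y(s, P);
      if (P.rest_AB > 0.0) {
        double e = std::sqrt(ex * ex + ey * ey);
        if (e > 1e-12) {
          double f = P.k_AB * (e - P.rest_AB) / e;
          fx[c] -= f * ex; fy[c] -= f * ey;
        }
      } else {
        fx[c] -= P.k_AB * ex; fy[c] -= P.k_AB * ey;
      }
    }
  }
}

// (5b) self-association springs between carboxysome centers, finite range
static void calc_self_forces(const State& S, const Pars& P,
                             std::vector<double>& fx, std::vector<double>& fy) {
  fx.assign(P.n_carb, 0.0); fy.assign(P.n_carb, 0.0);
  for (int c = 0; c < P.n_carb; ++c) {
    for (int d = c + 1; d < P.n_carb; ++d) {
      double dx = S.cx[d] - S.cx[c], dy = S.cy[d] - S.cy[c];
      double r = std::sqrt(dx * dx + dy * dy);
      if (r > P.self_range || r < 1e-12) continue;
      double f = P.k_self * (r - P.rest_self);  // > 0 attracts
      double ux = dx / r, uy = dy / r;
      fx[c] += f * ux; fy[c] += f * uy;
      fx[d] -= f * ux; fy[d] -= f * uy;
    }
  }
}

static inline double reflect_coord(double x, double L) {
  while (x < 0.0 || x > L) {
    if (x < 0.0) x = -x;
    if (x > L) x = 2.0 * L - x;
  }
  return x;
}

// (6) overdamped displacement + hard-core exclusion + specular reflection
static void do_displace(State& S, const Pars& P,
                        const std::vector<double>& fx, const std::vector<double>& fy,
                        bool noise) {
  for (int c = 0; c < P.n_carb; ++c) {
    double dx = fx[c] * P.mob * P.dt;
    double dy = fy[c] * P.mob * P.dt;
    if (noise && P.noise_sd > 0.0) {
      dx += P.noise_sd * norm_rand();
      dy += P.noise_sd * norm_rand();
    }
    S.cx[c] += dx; S.cy[c] += dy;
    if (!std::isfinite(S.cx[c]) || !std::isfinite(S.cy[c]))
      stop("non-finite carboxysome position at t = %g s; reduce run.dt", S.time);
  }
  for (int pass = 0; pass < 4; ++pass) {
    bool any = false;
    for (int c = 0; c < P.n_carb; ++c) {
      for (int d = c + 1; d < P.n_carb; ++d) {
        double dx = S.cx[d] - S.cx[c], dy = S.cy[d] - S.cy[c];
        double r = std::sqrt(dx * dx + dy * dy);
        if (r < P.diam - 1e-12) {
          any = true;
          double ux = 1.0, uy = 0.0;
          if (r > 1e-12) { ux = dx / r; uy = dy / r; }
          double push = 0.5 * (P.diam - r);
          S.cx[c] -= push * ux; S.cy[c] -= push * uy;
          S.cx[d] += push * ux; S.cy[d] += push * uy;
        }
      }
    }
    if (!any) break;
  }
  for (int c = 0; c < P.n_carb; ++c) {
    S.cx[c] = reflect_coord(S.cx[c], P.Lx);
    S.cy[c] = reflect_coord(S.cy[c], P.Ly);
  }
}

// (7) bond breaking: rate k_bond_off plus hard guard at max extension;
// broken McdA is ejected to the cytoplasm (stimulated release).
static void do_break(State& S, const Pars& P) {
  const double mx2 = P.max_ext * P.max_ext;
  for (int c = 0; c < P.n_carb; ++c) {
    for (int j = 0; j < P.n_mcdB; ++j) {
      int g = c * P.n_mcdB + j;
      int m = S.site_bond[g];
      if (m < 0) continue;
      int s = S.site[m];
      double ex = S.cx[c] + S.offx[g] - site_x(s, P);
      double ey = S.cy[c] + S.offy[g] - site_y(s, P);
      bool br = (ex * ex + ey * ey) > mx2;
      if (!br && P.p_off > 0.0) br = (unif_rand() < P.p_off);
      if (br) {
        S.site_bond[g] = -1;
        S.occ[s] = -1;
        S.site[m] = -1;
        S.a_bond_carb[m] = -1;
        S.a_bond_site[m] = -1;
      }
    }
  }
}

static void do_step(State& S, const Pars& P,
                    std::vector<double>& fx, std::vector<double>& fy,
                    std::vector<double>& gx, std::vector<double>& gy) {
  do_hop(S, P);
  do_rebind(S, P);
  do_unbind(S, P);
  do_form_bonds(S, P);
  calc_bond_forces(S, P, fx, fy);
  calc_self_forces(S, P, gx, gy);
  for (int c = 0; c < P.n_carb; ++c) { fx[c] += gx[c]; fy[c] += gy[c]; }
  do_displace(S, P, fx, fy, true);
  do_break(S, P);
}

// [[Rcpp::export]]
List cpp_init_state(List params) {
  Pars P = make_pars(params);
  State S;
  S.time = 0.0;
  double span = (P.n_carb - 1) * P.rest_self;
  if (span + P.diam > P.Lx || P.diam > P.Ly)
    stop("domain too small to place %d carboxysomes at contact spacing", P.n_carb);
  for (int c = 0; c < P.n_carb; ++c) {
    S.cx.push_back(P.Lx / 2.0 - span / 2.0 + c * P.rest_self);
    S.cy.push_back(P.Ly / 2.0);
  }
  double R = P.diam / 2.0;
  S.offx.assign((size_t)P.n_carb * P.n_mcdB, 0.0);
  S.offy.assign((size_t)P.n_carb * P.n_mcdB, 0.0);
  for (int c = 0; c < P.n_carb; ++c) {
    for (int j = 0; j < P.n_mcdB; ++j) {
      double rr = R * std::sqrt(unif_rand());
      double th = 2.0 * M_PI * unif_rand();
      S.offx[(size_t)c * P.n_mcdB + j] = rr * std::cos(th);
      S.offy[(size_t)c * P.n_mcdB + j] = rr * std::sin(th);
    }
  }
  double denom = P.k_rebind + P.k_off;
  double fb = (denom > 0.0) ? P.k_rebind / denom : 1.0;
  int n_bound = (int) std::lround(fb * P.n_mcdA);
  if (n_bound > P.nsites)
    stop("steady-state bound McdA count (%d) exceeds lattice capacity (%d)", n_bound, P.nsites);
  S.occ.assign(P.nsites, -1);
  S.site.assign(P.n_mcdA, -1);
  S.a_bond_carb.assign(P.n_mcdA, -1);
  S.a_bond_site.assign(P.n_mcdA, -1);
  S.site_bond.assign((size_t)P.n_carb * P.n_mcdB, -1);
  // partial Fisher-Yates: first n_bound entries are a uniform random sample
  // of distinct sites
  std::vector<int> sites(P.nsites);
  for (int s = 0; s < P.nsites; ++s) sites[s] = s;
  for (int i = 0; i < n_bound; ++i) {
    int pick = i + rand_int(P.nsites - i);
    std::swap(sites[i], sites[pick]);
    S.site[i] = sites[i];
    S.occ[sites[i]] = i;
  }
  return to_list(S, P);
}

// [[Rcpp::export]]
List cpp_step(List state, List params) {
  Pars P = make_pars(params);
  State S = from_list(state, P);
  std::vector<double> fx, fy, gx, gy;
  do_step(S, P, fx, fy, gx, gy);
  S.time += P.dt;
  return to_list(S, P);
}

// [[Rcpp::export]]
List cpp_advance(List state, List params, int n_steps, int record_every,
                 bool track_annulus = false, double r_in = 0.0, double r_out = 0.0) {
  Pars P = make_pars(params);
  State S = from_list(state, P);
  double t0 = S.time;
  int n_rec = (record_every > 0) ? n_steps / record_every : 0;
  NumericMatrix rec(n_rec, 2 + 3 * P.n_carb);
  NumericVector ann_lead(track_annulus ? n_rec : 0);
  NumericVector ann_trail(track_annulus ? n_rec : 0);
  double px = (P.n_carb > 0) ? S.cx[0] : 0.0;
  double py = (P.n_carb > 0) ? S.cy[0] : 0.0;
  std::vector<double> fx, fy, gx, gy;
  int r = 0;
  for (int step = 1; step <= n_steps; ++step) {
    do_step(S, P, fx, fy, gx, gy);
    S.time = t0 + step * P.dt;
    if (record_every > 0 && step % record_every == 0) {
      rec(r, 0) = S.time;
      int n_on = 0;
      for (int i = 0; i < P.n_mcdA; ++i) if (S.site[i] >= 0) ++n_on;
      rec(r, 1) = n_on;
      for (int c = 0; c < P.n_carb; ++c) {
        int nb = 0;
        for (int j = 0; j < P.n_mcdB; ++j)
          if (S.site_bond[c * P.n_mcdB + j] >= 0) ++nb;
        rec(r, 2 + 3 * c) = S.cx[c];
        rec(r, 3 + 3 * c) = S.cy[c];
        rec(r, 4 + 3 * c) = nb;
      }
      if (track_annulus && P.n_carb > 0) {
        double vx = S.cx[0] - px, vy = S.cy[0] - py;
        double vn = std::sqrt(vx * vx + vy * vy);
        if (vn > 1e-9) {
          double lead = 0.0, trail = 0.0;
          double r1s = r_in * r_in, r2s = r_out * r_out;
          for (int i = 0; i < P.n_mcdA; ++i) {
            if (S.site[i] < 0) continue;
            double dx = site_x(S.site[i], P) - S.cx[0];
            double dy = site_y(S.site[i], P) - S.cy[0];
            double d2 = dx * dx + dy * dy;
            if (d2 < r1s || d2 > r2s) continue;
            if (dx * vx + dy * vy >= 0.0) lead += 1.0; else trail += 1.0;
          }
          ann_lead[r] = lead; ann_trail[r] = trail;
        } else {
          ann_lead[r] = NA_REAL; ann_trail[r] = NA_REAL;
        }
        px = S.cx[0]; py = S.cy[0];
      }
      ++r;
    }
    if ((step & 8191) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["state"] = to_list(S, P), _["records"] = rec,
                      _["annulus_lead"] = ann_lead, _["annulus_trail"] = ann_trail);
}

// [[Rcpp::export]]
List cpp_hop(List state, List params) {
  Pars P = make_pars(params);
  State S = from_list(state, P);
  do_hop(S, P);
  return to_list(S, P);
}

// [[Rcpp::export]]
List cpp_rebind(List state, List params) {
  Pars P = make_pars(params);
  State S = from_list(state, P);
  do_rebind(S, P);
  return to_list(S, P);
}

// [[Rcpp::export]]
List cpp_unbind(List state, List params) {
  Pars P = make_pars(params);
  State S = from_list(state, P);
  do_unbind(S, P);
  return to_list(S, P);
}

// [[Rcpp::export]]
List cpp_form_bonds(List state, List params) {
  Pars P = make_pars(params);
  State S = from_list(state, P);
  do_form_bonds(S, P);
  return to_list(S, P);
}

// [[Rcpp::export]]
List cpp_break_bonds(List state, List params) {
  Pars P = make_pars(params);
  State S = from_list(state, P);
  do_break(S, P);
  return to_list(S, P);
}

// [[Rcpp::export]]
NumericMatrix cpp_bond_forces(List state, List params) {
  Pars P = make_pars(params);
  State S = from_list(state, P);
  std::vector<double> fx, fy;
  calc_bond_forces(S, P, fx, fy);
  NumericMatrix out(P.n_carb, 2);
  for (int c = 0; c < P.n_carb; ++c) { out(c, 0) = fx[c]; out(c, 1) = fy[c]; }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_self_forces(List state, List params) {
  Pars P = make_pars(params);
  State S = from_list(state, P);
  std::vector<double> fx, fy;
  calc_self_forces(S, P, fx, fy);
  NumericMatrix out(P.n_carb, 2);
  for (int c = 0; c < P.n_carb; ++c) { out(c, 0) = fx[c]; out(c, 1) = fy[c]; }
  return out;
}

// [[Rcpp::export]]
List cpp_displace(List state, NumericMatrix forces, List params, bool noise = true) {
  Pars P = make_pars(params);
  State S = from_list(state, P);
  if (forces.nrow() != P.n_carb || forces.ncol() != 2)
    stop("forces must be an n_carboxysomes x 2 matrix");
  std::vector<double> fx(P.n_carb), fy(P.n_carb);
  for (int c = 0; c < P.n_carb; ++c) { fx[c] = forces(c, 0); fy[c] = forces(c, 1); }
  do_displace(S, P, fx, fy, noise);
  return to_list(S, P);
}

// Cross-reference consistency of occupancy, sites and bonds; returns a
// character vector of violations (empty if consistent).
// [[Rcpp::export]]
CharacterVector cpp_check_state(List state, List params) {
  Pars P = make_pars(params);
  State S = from_list(state, P);
  std::vector<std::string> bad;
  int n_on = 0;
  for (int i = 0; i < P.n_mcdA; ++i) {
    if (S.site[i] >= 0) {
      ++n_on;
      if (S.site[i] >= P.nsites) bad.push_back("mcda_site out of range");
      else if (S.occ[S.site[i]] != i) bad.push_back("occupancy does not match mcda_site");
    } else if (S.a_bond_carb[i] >= 0) {
      bad.push_back("cytoplasmic McdA carries a bond");
    }
  }
  int n_occ = 0;
  for (int s = 0; s < P.nsites; ++s) {
    if (S.occ[s] >= 0) {
      ++n_occ;
      if (S.site[S.occ[s]] != s) bad.push_back("mcda_site does not match occupancy");
    }
  }
  if (n_occ != n_on) bad.push_back("occupied site count != nucleoid McdA count");
  for (int c = 0; c < P.n_carb; ++c) {
    for (int j = 0; j < P.n_mcdB; ++j) {
      int m = S.site_bond[c * P.n_mcdB + j];
      if (m < 0) continue;
      if (S.a_bond_carb[m] != c || S.a_bond_site[m] != j)
        bad.push_back("bond table and McdA bond back-references disagree");
      if (S.site[m] < 0) bad.push_back("bonded McdA is not on the nucleoid");
    }
  }
  return wrap(bad);
}
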