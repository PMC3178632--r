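// Brownian-dynamics core: pair potentials with analytic gradients, Verlet
// pair list, overdamped Langevin stepping for positions and polarization
// vectors, and stochastic hydrolysis / depolymerization / severing chemistry.
// Units: lengths in the subunit diameter a, energies in kT, times in
// tau0 = a^2/D0 (gamma0 = kT*tau0/a^2 = 1 in these units by default).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <array>
#include <cmath>
#include <algorithm>
#include <string>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG
// xoshiro256++ with splitmix64 seeding and a 128-layer ziggurat normal
// sampler: fast, high-quality, and fully portable, so a seed determines the
// identical noise stream on every platform.

struct RNG {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t& x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit RNG(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
    zigset();
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }

  // Marsaglia-Tsang ziggurat (128 layers)
  uint32_t kn[128];
  double wn[128], fn[128];
  void zigset() {
    double m1 = 2147483648.0, dn = 3.442619855899, tn = dn,
           vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1); kn[1] = 0;
    wn[0] = q / m1; wn[127] = dn / m1;
    fn[0] = 1.0; fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      wn[i] = dn / m1;
      fn[i] = std::exp(-0.5 * dn * dn);
    }
  }
  double normal() {
    for (;;) {
      int32_t hz = (int32_t)(uint32_t)next();
      int iz = hz & 127;
      if ((uint32_t)std::abs(hz) < kn[iz]) return hz * wn[iz];
      // slow path: tail or wedge
      const double r = 3.442619855899;
      if (iz == 0) {
        double x, y;
        do {
          x = -std::log(unif()) / r;
          y = -std::log(unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -(r + x);
      }
      double x = hz * wn[iz];
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * x * x))
        return x;
    }
  }
};

// species codes
static const int SP_PARA = 0, SP_PARB_BIND = 1, SP_PARB_INERT = 2;
// nucleotide codes
static const int NUC_ATP = 0, NUC_ADP = 1, NUC_NONE = 2;
// event kinds
static const int EV_HYDROLYSIS = 0, EV_DEPOLY = 1, EV_SEVER = 2;

struct FF {
  double a, k_bond, k_crosslink, d0, k_bend_parA, k_bend_parB;
  double k_align, cos_theta0, k_helix_nn, k_helix_nnn;
  double cpsi_nn_A, cpsi_nnn_A, cpsi_nn_B, cpsi_nnn_B;
  double eps_b, r_b, range_b, w_ang_A, w_ang_B;
  int binding_form; // 0 = oriented (ParA & ParB polar), 1 = no ParB polarization factor
  double wall_radius, k_wall; // <=0: no confinement
};

static FF parse_ff(const List& l) {
  FF f;
  f.a = as<double>(l["a"]);
  f.k_bond = as<double>(l["k_bond"]);
  f.k_crosslink = as<double>(l["k_crosslink"]);
  f.d0 = as<double>(l["d0"]);
  f.k_bend_parA = as<double>(l["k_bend_parA"]);
  f.k_bend_parB = as<double>(l["k_bend_parB"]);
  f.k_align = as<double>(l["k_align"]);
  f.cos_theta0 = std::cos(as<double>(l["theta0_deg"]) * M_PI / 180.0);
  f.k_helix_nn = as<double>(l["k_helix_nn"]);
  f.k_helix_nnn = as<double>(l["k_helix_nnn"]);
  f.cpsi_nn_A = std::cos(as<double>(l["psi_nn_parA_deg"]) * M_PI / 180.0);
  f.cpsi_nnn_A = std::cos(as<double>(l["psi_nnn_parA_deg"]) * M_PI / 180.0);
  f.cpsi_nn_B = std::cos(as<double>(l["psi_nn_parB_deg"]) * M_PI / 180.0);
  f.cpsi_nnn_B = std::cos(as<double>(l["psi_nnn_parB_deg"]) * M_PI / 180.0);
  f.eps_b = as<double>(l["eps_b"]);
  f.r_b = as<double>(l["r_b"]);
  f.range_b = as<double>(l["range_b"]);
  f.w_ang_A = as<double>(l["w_ang_parA"]);
  f.w_ang_B = as<double>(l["w_ang_parB"]);
  f.binding_form = as<int>(l["binding_form_code"]);
  f.wall_radius = l.containsElementNamed("wall_radius") ? as<double>(l["wall_radius"]) : -1.0;
  f.k_wall = l.containsElementNamed("k_wall") ? as<double>(l["k_wall"]) : 50.0;
  return f;
}

struct Vec3 { double x, y, z; };
static inline Vec3 v3(double x, double y, double z) { Vec3 v; v.x = x; v.y = y; v.z = z; return v; }
static inline Vec3 operator+(Vec3 a, Vec3 b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline Vec3 operator-(Vec3 a, Vec3 b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline Vec3 operator*(double s, Vec3 a) { return v3(s * a.x, s * a.y, s * a.z); }
static inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 cross(Vec3 a, Vec3 b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(Vec3 a) { return std::sqrt(dot(a, a)); }

// ---------------------------------------------------------------- pair terms

// WCA repulsion, contact (zero) at r = a, epsilon = 1 kT.
static void ev_term(double r, const FF& ff, double& U, double& dUdr) {
  U = 0; dUdr = 0;
  if (r >= ff.a) return;
  double sig = ff.a * std::pow(2.0, -1.0 / 6.0);
  double sr2 = (sig / r) * (sig / r);
  double sr6 = sr2 * sr2 * sr2;
  U = 4.0 * (sr6 * sr6 - sr6) + 1.0;
  dUdr = 24.0 * (sr6 - 2.0 * sr6 * sr6) / r;
}

static void harm_term(double r, double k, double r0, double& U, double& dUdr) {
  U = 0.5 * k * (r - r0) * (r - r0);
  dUdr = k * (r - r0);
}

// Oriented short-ranged ParA-ParB binding: U = -eps * f(r) * g(ca) * h(cb)
// with radial well f = (1-s^2)^2, s = (r - r_b)/(range_b - r_b), and Gaussian
// angular factors in the alignment of the polarization vectors with the
// inter-subunit axis.  e points from the ParA subunit i to the ParB subunit j.
// Outputs: energy, force on j (force on i = -Fj), and dU/dp gradients.
static void binding_term(Vec3 ri, Vec3 rj, Vec3 pi, Vec3 pj, const FF& ff,
                         double& U, Vec3& Fj, Vec3& gpi, Vec3& gpj) {
  U = 0; Fj = v3(0, 0, 0); gpi = v3(0, 0, 0); gpj = v3(0, 0, 0);
  Vec3 d = rj - ri;
  double r = norm(d);
  if (r <= 0 || r >= ff.range_b) return;
  double wr = ff.range_b - ff.r_b;
  double s = (r - ff.r_b) / wr;
  if (std::fabs(s) >= 1.0) return;
  double oms = 1.0 - s * s;
  double f = oms * oms;
  double dfdr = -4.0 * s * oms / wr;
  Vec3 e = (1.0 / r) * d;
  double ca = dot(pi, e);
  double wa2 = ff.w_ang_A * ff.w_ang_A;
  double ga = std::exp(-(1.0 - ca) * (1.0 - ca) / (2.0 * wa2));
  double dga = ga * (1.0 - ca) / wa2;
  double cb = 0, gb = 1, dgb = 0;
  if (ff.binding_form == 0) {
    cb = -dot(pj, e);
    double wb2 = ff.w_ang_B * ff.w_ang_B;
    gb = std::exp(-(1.0 - cb) * (1.0 - cb) / (2.0 * wb2));
    dgb = gb * (1.0 - cb) / wb2;
  }
  U = -ff.eps_b * f * ga * gb;
  // dU/drj = -eps [ f'(r) e ga gb + f ( dga * dca/drj * gb + ga * dgb * dcb/drj ) ]
  Vec3 dca = (1.0 / r) * (pi - ca * e);
  Vec3 grad = (dfdr * ga * gb) * e + (f * dga * gb) * dca;
  if (ff.binding_form == 0) {
    Vec3 dcb = (-1.0 / r) * (pj + cb * e);
    grad = grad + (f * ga * dgb) * dcb;
  }
  grad = (-ff.eps_b) * grad;      // = dU/drj
  Fj = (-1.0) * grad;
  gpi = (-ff.eps_b * f * dga * gb) * e;
  if (ff.binding_form == 0) gpj = (ff.eps_b * f * ga * dgb) * e; // dcb/dpj = -e
}

// bending over triple (prev, mid, next): U = k (1 - cos theta)
static void bend_term(Vec3 rp, Vec3 rm, Vec3 rn, double k,
                      double& U, Vec3& Fp, Vec3& Fm, Vec3& Fn) {
  Vec3 b1 = rm - rp, b2 = rn - rm;
  double l1 = norm(b1), l2 = norm(b2);
  Vec3 u = (1.0 / l1) * b1, v = (1.0 / l2) * b2;
  double c = dot(u, v);
  U = k * (1.0 - c);
  // dc/drp = -(v - c u)/l1 ; dc/drn = (u - c v)/l2 ; dU/dx = -k dc/dx
  Vec3 dcdp = (-1.0 / l1) * (v - c * u);
  Vec3 dcdn = (1.0 / l2) * (u - c * v);
  Fp = k * dcdp; // F = -dU/drp = k dc/drp
  Fn = k * dcdn;
  Fm = (-1.0) * (Fp + Fn);
}

// alignment of polarization p to a chain bond b (vector between adjacent
// subunits, oriented tip->anchor): U = (k/2)(p.bhat - cos theta0)^2.
// Returns energy, dU/dp, and dU/db (force on bond endpoints follows).
static void align_term(Vec3 p, Vec3 b, double k, double c0,
                       double& U, Vec3& gp, Vec3& gb) {
  double l = norm(b);
  Vec3 bh = (1.0 / l) * b;
  double c = dot(p, bh);
  U = 0.5 * k * (c - c0) * (c - c0);
  gp = (k * (c - c0)) * bh;
  gb = (k * (c - c0) / l) * (p - c * bh);
}

// helical coupling between polarizations: U = (k/2)(pi.pj - cos psi)^2
static void helix_term(Vec3 pi, Vec3 pj, double k, double cpsi,
                       double& U, Vec3& gpi, Vec3& gpj) {
  double c = dot(pi, pj);
  U = 0.5 * k * (c - cpsi) * (c - cpsi);
  gpi = (k * (c - cpsi)) * pj;
  gpj = (k * (c - cpsi)) * pi;
}

// ---------------------------------------------------------------- system

struct Sys {
  int N;
  std::vector<double> px, py, pz;    // positions
  std::vector<double> ux, uy, uz;    // polarizations (unit)
  std::vector<int> species, nuc;
  std::vector<double> alpha;
  std::vector<char> anchored;
  std::vector<std::vector<int>> chains;  // 0-based subunit ids, tip -> anchor
  std::vector<char> chain_anchored;      // built with an anchored end
  std::vector<std::array<int, 2>> xl;    // crosslinks
  std::vector<int> chain_id, chain_idx;  // -1 for monomers
  double t;
  int n_para0;
};

static void reindex_chains(Sys& S) {
  std::fill(S.chain_id.begin(), S.chain_id.end(), -1);
  std::fill(S.chain_idx.begin(), S.chain_idx.end(), -1);
  for (size_t c = 0; c < S.chains.size(); ++c)
    for (size_t k = 0; k < S.chains[c].size(); ++k) {
      S.chain_id[S.chains[c][k]] = (int)c;
      S.chain_idx[S.chains[c][k]] = (int)k;
    }
}

static Sys parse_sys(NumericMatrix pos, NumericMatrix pol, IntegerVector species,
                     IntegerVector nuc, NumericVector alpha, LogicalVector anchored,
                     List chains, LogicalVector chainAnchored, IntegerMatrix xlinks,
                     double t, int n_para0) {
  Sys S;
  S.N = pos.nrow();
  S.px.resize(S.N); S.py.resize(S.N); S.pz.resize(S.N);
  S.ux.resize(S.N); S.uy.resize(S.N); S.uz.resize(S.N);
  S.species.resize(S.N); S.nuc.resize(S.N); S.alpha.resize(S.N); S.anchored.resize(S.N);
  S.chain_id.assign(S.N, -1); S.chain_idx.assign(S.N, -1);
  for (int i = 0; i < S.N; ++i) {
    S.px[i] = pos(i, 0); S.py[i] = pos(i, 1); S.pz[i] = pos(i, 2);
    S.ux[i] = pol(i, 0); S.uy[i] = pol(i, 1); S.uz[i] = pol(i, 2);
    S.species[i] = species[i]; S.nuc[i] = nuc[i];
    S.alpha[i] = alpha[i]; S.anchored[i] = anchored[i] ? 1 : 0;
  }
  for (int c = 0; c < chains.size(); ++c) {
    IntegerVector ch = chains[c];
    std::vector<int> v(ch.size());
    for (int k = 0; k < ch.size(); ++k) v[k] = ch[k] - 1;
    S.chains.push_back(v);
    S.chain_anchored.push_back(chainAnchored[c] ? 1 : 0);
  }
  for (int m = 0; m < xlinks.nrow(); ++m)
    S.xl.push_back({xlinks(m, 0) - 1, xlinks(m, 1) - 1});
  S.t = t; S.n_para0 = n_para0;
  reindex_chains(S);
  return S;
}

static inline Vec3 POS(const Sys& S, int i) { return v3(S.px[i], S.py[i], S.pz[i]); }
static inline Vec3 POL(const Sys& S, int i) { return v3(S.ux[i], S.uy[i], S.uz[i]); }

// eligibility of ParA subunits for ParB binding (mirrors R eligible_binders())
static void compute_bindable(const Sys& S, int binding_mode, std::vector<char>& b) {
  b.assign(S.N, 0);
  if (binding_mode == 0) {
    // SIDE: every polymerized ParA subunit.  Hydrolyzed subunits keep their
    // ParB affinity until they depolymerize; only free monomers lose it.
    // (An ADP tip zone that stopped binding would shed the ParB polymer
    // whenever depolymerization is slow, and no translocation would occur.)
    for (int i = 0; i < S.N; ++i)
      if (S.species[i] == SP_PARA && S.chain_id[i] >= 0) b[i] = 1;
  } else {                            // TIP_ONLY: free-tip subunit(s)
    for (size_t c = 0; c < S.chains.size(); ++c) {
      const std::vector<int>& ch = S.chains[c];
      if (ch.empty() || S.species[ch[0]] != SP_PARA) continue;
      b[ch.front()] = 1;
      if (!S.chain_anchored[c] && ch.size() > 1) b[ch.back()] = 1;
    }
  }
}

// ---------------------------------------------------------------- pair list

struct PairList {
  std::vector<std::array<int, 2>> ev_pairs;    // all species, within a + skin
  std::vector<std::array<int, 2>> bind_pairs;  // (ParA, ParB_BIND), within range_b + skin
  std::vector<double> ref_x, ref_y, ref_z;
  double skin = 1.0;
  bool valid = false;
};

// chain 1-2 neighbors are excluded from excluded volume: the harmonic bond
// governs that distance (standard bead-spring exclusion)
static inline bool bonded_12(const Sys& S, int i, int j) {
  return S.chain_id[i] >= 0 && S.chain_id[i] == S.chain_id[j] &&
         std::abs(S.chain_idx[i] - S.chain_idx[j]) == 1;
}

static void build_pairlist(const Sys& S, const FF& ff, PairList& pl) {
  double rc_ev = ff.a + pl.skin, rc_b = ff.range_b + pl.skin;
  double rc_ev2 = rc_ev * rc_ev, rc_b2 = rc_b * rc_b;
  pl.ev_pairs.clear(); pl.bind_pairs.clear();
  for (int i = 0; i < S.N; ++i)
    for (int j = i + 1; j < S.N; ++j) {
      double dx = S.px[i] - S.px[j], dy = S.py[i] - S.py[j], dz = S.pz[i] - S.pz[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < rc_ev2 && !bonded_12(S, i, j)) pl.ev_pairs.push_back({i, j});
      if (d2 < rc_b2) {
        if (S.species[i] == SP_PARA && S.species[j] == SP_PARB_BIND)
          pl.bind_pairs.push_back({i, j});
        else if (S.species[j] == SP_PARA && S.species[i] == SP_PARB_BIND)
          pl.bind_pairs.push_back({j, i});
      }
    }
  pl.ref_x = S.px; pl.ref_y = S.py; pl.ref_z = S.pz;
  pl.valid = true;
}

static bool pairlist_stale(const Sys& S, const PairList& pl) {
  if (!pl.valid) return true;
  double lim = 0.25 * pl.skin * pl.skin; // (skin/2)^2
  for (int i = 0; i < S.N; ++i) {
    double dx = S.px[i] - pl.ref_x[i], dy = S.py[i] - pl.ref_y[i], dz = S.pz[i] - pl.ref_z[i];
    if (dx * dx + dy * dy + dz * dz > lim) return true;
  }
  return false;
}

// ---------------------------------------------------------------- forces

struct ForceOut {
  std::vector<double> fx, fy, fz;   // forces
  std::vector<double> gx, gy, gz;   // dU/dp accumulators
  std::vector<double> maxbind;      // strongest |binding energy| per subunit
  std::vector<double> minE_parb;      // most negative pair binding energy per ParB
  std::vector<double> minE_parb_anch; // same, restricted to anchored-chain ParA
  double U = 0;
};

static void compute_forces(const Sys& S, const FF& ff, const std::vector<char>& bindable,
                           const PairList* pl, ForceOut& out,
                           std::vector<std::array<double, 3>>* pair_table) {
  int N = S.N;
  out.fx.assign(N, 0); out.fy.assign(N, 0); out.fz.assign(N, 0);
  out.gx.assign(N, 0); out.gy.assign(N, 0); out.gz.assign(N, 0);
  out.maxbind.assign(N, 0); out.minE_parb.assign(N, 0);
  out.minE_parb_anch.assign(N, 0);
  out.U = 0;

  auto addF = [&](int i, Vec3 f) { out.fx[i] += f.x; out.fy[i] += f.y; out.fz[i] += f.z; };
  auto addG = [&](int i, Vec3 g) { out.gx[i] += g.x; out.gy[i] += g.y; out.gz[i] += g.z; };

  // non-bonded: excluded volume (all pairs) + binding (eligible ParA x ParB_BIND)
  double a2 = ff.a * ff.a, rb2 = ff.range_b * ff.range_b;
  auto do_ev = [&](int i, int j) {
    double dx = S.px[i] - S.px[j], dy = S.py[i] - S.py[j], dz = S.pz[i] - S.pz[j];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 >= a2) return;
    if (d2 <= 1e-24) stop("overlapping subunit centers (ids %d, %d)", i + 1, j + 1);
    double r = std::sqrt(d2);
    double U, dUdr;
    ev_term(r, ff, U, dUdr);
    double s = -dUdr / r;
    out.fx[i] += s * dx; out.fy[i] += s * dy; out.fz[i] += s * dz;
    out.fx[j] -= s * dx; out.fy[j] -= s * dy; out.fz[j] -= s * dz;
    out.U += U;
  };
  auto do_bind = [&](int ia, int jb) {
    if (!bindable[ia]) return;
    double dx = S.px[ia] - S.px[jb], dy = S.py[ia] - S.py[jb], dz = S.pz[ia] - S.pz[jb];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 >= rb2) return;
    double Ub; Vec3 Fj, gpi, gpj;
    binding_term(POS(S, ia), POS(S, jb), POL(S, ia), POL(S, jb), ff, Ub, Fj, gpi, gpj);
    if (Ub != 0) {
      addF(jb, Fj); addF(ia, (-1.0) * Fj);
      addG(ia, gpi); addG(jb, gpj);
      out.U += Ub;
      double mag = -Ub;
      if (mag > out.maxbind[ia]) out.maxbind[ia] = mag;
      if (mag > out.maxbind[jb]) out.maxbind[jb] = mag;
      if (Ub < out.minE_parb[jb]) out.minE_parb[jb] = Ub;
      // the "anchored bundle" excludes bare single-subunit stubs (the
      // immortal anchored terminals); a filament needs at least one bond
      if (S.chain_id[ia] >= 0 && S.chain_anchored[S.chain_id[ia]] &&
          S.chains[S.chain_id[ia]].size() >= 2 &&
          Ub < out.minE_parb_anch[jb]) out.minE_parb_anch[jb] = Ub;
      if (pair_table) pair_table->push_back({(double)ia + 1, (double)jb + 1, Ub});
    }
  };
  if (pl) {
    for (const auto& p : pl->ev_pairs) do_ev(p[0], p[1]);
    if (ff.eps_b > 0)
      for (const auto& p : pl->bind_pairs) do_bind(p[0], p[1]);
  } else {
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        if (!bonded_12(S, i, j)) do_ev(i, j);
        if (ff.eps_b > 0) {
          if (S.species[i] == SP_PARA && S.species[j] == SP_PARB_BIND) do_bind(i, j);
          else if (S.species[j] == SP_PARA && S.species[i] == SP_PARB_BIND) do_bind(j, i);
        }
      }
  }

  // bonded terms per chain; bond vectors and lengths are computed once and
  // shared by the bond, alignment, and bending terms
  static thread_local std::vector<double> bx, by, bz, br;
  for (size_t c = 0; c < S.chains.size(); ++c) {
    const std::vector<int>& ch = S.chains[c];
    int L = (int)ch.size();
    if (L < 2) continue;
    bool isA = S.species[ch[0]] == SP_PARA;
    double kbend = isA ? ff.k_bend_parA : ff.k_bend_parB;
    double cnn = isA ? ff.cpsi_nn_A : ff.cpsi_nn_B;
    double cnnn = isA ? ff.cpsi_nnn_A : ff.cpsi_nnn_B;
    int nb = L - 1;
    if ((int)bx.size() < nb) { bx.resize(nb); by.resize(nb); bz.resize(nb); br.resize(nb); }
    for (int k = 0; k < nb; ++k) {
      int i = ch[k], j = ch[k + 1];
      double dx = S.px[j] - S.px[i], dy = S.py[j] - S.py[i], dz = S.pz[j] - S.pz[i];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      bx[k] = dx; by[k] = dy; bz[k] = dz; br[k] = r;
      // harmonic bond about rest length a
      double dUdr = ff.k_bond * (r - ff.a);
      double s = dUdr / r;
      out.fx[i] += s * dx; out.fy[i] += s * dy; out.fz[i] += s * dz;
      out.fx[j] -= s * dx; out.fy[j] -= s * dy; out.fz[j] -= s * dz;
      out.U += 0.5 * ff.k_bond * (r - ff.a) * (r - ff.a);
      // polarization alignment of both endpoints to this bond (inert ParB
      // subunits carry no binding site, so their orientation is free)
      if (ff.k_align > 0) {
        for (int which = 0; which < 2; ++which) {
          int q = which == 0 ? i : j;
          if (S.species[q] == SP_PARB_INERT) continue;
          double cb = (S.ux[q] * dx + S.uy[q] * dy + S.uz[q] * dz) / r;
          double dev = cb - ff.cos_theta0;
          out.U += 0.5 * ff.k_align * dev * dev;
          double gpl = ff.k_align * dev / r; // dU/dp = gpl * b
          out.gx[q] += gpl * dx; out.gy[q] += gpl * dy; out.gz[q] += gpl * dz;
          // dU/db = (k dev / r) (p - cb bhat); force on i = +dU/db, on j = -dU/db
          double gb0 = ff.k_align * dev / r;
          double gbx = gb0 * (S.ux[q] - cb * dx / r);
          double gby = gb0 * (S.uy[q] - cb * dy / r);
          double gbz = gb0 * (S.uz[q] - cb * dz / r);
          out.fx[i] += gbx; out.fy[i] += gby; out.fz[i] += gbz;
          out.fx[j] -= gbx; out.fy[j] -= gby; out.fz[j] -= gbz;
        }
      }
      if (ff.k_helix_nn > 0 && S.species[i] != SP_PARB_INERT &&
          S.species[j] != SP_PARB_INERT) {
        double cp = S.ux[i] * S.ux[j] + S.uy[i] * S.uy[j] + S.uz[i] * S.uz[j];
        double dev = cp - cnn;
        out.U += 0.5 * ff.k_helix_nn * dev * dev;
        double g = ff.k_helix_nn * dev;
        out.gx[i] += g * S.ux[j]; out.gy[i] += g * S.uy[j]; out.gz[i] += g * S.uz[j];
        out.gx[j] += g * S.ux[i]; out.gy[j] += g * S.uy[i]; out.gz[j] += g * S.uz[i];
      }
    }
    for (int k = 0; k + 1 < nb; ++k) {
      int ip = ch[k], im = ch[k + 1], in_ = ch[k + 2];
      if (kbend > 0) {
        double l1 = br[k], l2 = br[k + 1];
        double ux1 = bx[k] / l1, uy1 = by[k] / l1, uz1 = bz[k] / l1;
        double ux2 = bx[k + 1] / l2, uy2 = by[k + 1] / l2, uz2 = bz[k + 1] / l2;
        double cth = ux1 * ux2 + uy1 * uy2 + uz1 * uz2;
        out.U += kbend * (1.0 - cth);
        double fpx = (-kbend / l1) * (ux2 - cth * ux1);
        double fpy = (-kbend / l1) * (uy2 - cth * uy1);
        double fpz = (-kbend / l1) * (uz2 - cth * uz1);
        double fnx = (kbend / l2) * (ux1 - cth * ux2);
        double fny = (kbend / l2) * (uy1 - cth * uy2);
        double fnz = (kbend / l2) * (uz1 - cth * uz2);
        out.fx[ip] += fpx; out.fy[ip] += fpy; out.fz[ip] += fpz;
        out.fx[in_] += fnx; out.fy[in_] += fny; out.fz[in_] += fnz;
        out.fx[im] -= fpx + fnx; out.fy[im] -= fpy + fny; out.fz[im] -= fpz + fnz;
      }
      if (ff.k_helix_nnn > 0 && S.species[ip] != SP_PARB_INERT &&
          S.species[in_] != SP_PARB_INERT) {
        double cp = S.ux[ip] * S.ux[in_] + S.uy[ip] * S.uy[in_] + S.uz[ip] * S.uz[in_];
        double dev = cp - cnnn;
        out.U += 0.5 * ff.k_helix_nnn * dev * dev;
        double g = ff.k_helix_nnn * dev;
        out.gx[ip] += g * S.ux[in_]; out.gy[ip] += g * S.uy[in_]; out.gz[ip] += g * S.uz[in_];
        out.gx[in_] += g * S.ux[ip]; out.gy[in_] += g * S.uy[ip]; out.gz[in_] += g * S.uz[ip];
      }
    }
  }

  // crosslinks
  for (const auto& x : S.xl) {
    int i = x[0], j = x[1];
    Vec3 d = POS(S, j) - POS(S, i);
    double r = norm(d);
    double U, dUdr;
    harm_term(r, ff.k_crosslink, ff.d0, U, dUdr);
    Vec3 f = (dUdr / r) * d;
    addF(i, f); addF(j, (-1.0) * f);
    out.U += U;
  }

  // optional cylindrical confinement (harmonic wall about the x axis)
  if (ff.wall_radius > 0) {
    for (int i = 0; i < N; ++i) {
      double rho = std::sqrt(S.py[i] * S.py[i] + S.pz[i] * S.pz[i]);
      if (rho > ff.wall_radius) {
        double exc = rho - ff.wall_radius;
        out.U += 0.5 * ff.k_wall * exc * exc;
        double fmag = -ff.k_wall * exc / rho;
        out.fy[i] += fmag * S.py[i];
        out.fz[i] += fmag * S.pz[i];
      }
    }
  }
}

// ------------------------------------------------------------- exported: pairs

// [[Rcpp::export]]
List ff_pair_cpp(std::string kind, NumericVector ri, NumericVector rj,
                 NumericVector pi_, NumericVector pj_, List ffl) {
  FF ff = parse_ff(ffl);
  Vec3 a = v3(ri[0], ri[1], ri[2]), b = v3(rj[0], rj[1], rj[2]);
  Vec3 d = a - b;
  double r = norm(d);
  double U = 0; Vec3 Fi = v3(0, 0, 0), gpi = v3(0, 0, 0), gpj = v3(0, 0, 0);
  if (kind == "binding") {
    Vec3 pi = v3(pi_[0], pi_[1], pi_[2]), pj = v3(pj_[0], pj_[1], pj_[2]);
    Vec3 Fj;
    binding_term(a, b, pi, pj, ff, U, Fj, gpi, gpj);
    Fi = (-1.0) * Fj;
  } else {
    if (r <= 1e-12) stop("overlapping subunit centers");
    double dUdr = 0;
    if (kind == "ev") { if (r < ff.a) ev_term(r, ff, U, dUdr); }
    else if (kind == "bond") harm_term(r, ff.k_bond, ff.a, U, dUdr);
    else if (kind == "crosslink") harm_term(r, ff.k_crosslink, ff.d0, U, dUdr);
    else stop("unknown pair kind '%s'", kind.c_str());
    Fi = (-dUdr / r) * d;
  }
  Vec3 pi = v3(pi_[0], pi_[1], pi_[2]), pj = v3(pj_[0], pj_[1], pj_[2]);
  Vec3 ti = (-1.0) * cross(pi, gpi), tj = (-1.0) * cross(pj, gpj);
  return List::create(_["energy"] = U,
                      _["force_i"] = NumericVector::create(Fi.x, Fi.y, Fi.z),
                      _["force_j"] = NumericVector::create(-Fi.x, -Fi.y, -Fi.z),
                      _["dUdp_i"] = NumericVector::create(gpi.x, gpi.y, gpi.z),
                      _["dUdp_j"] = NumericVector::create(gpj.x, gpj.y, gpj.z),
                      _["torque_i"] = NumericVector::create(ti.x, ti.y, ti.z),
                      _["torque_j"] = NumericVector::create(tj.x, tj.y, tj.z));
}

// [[Rcpp::export]]
List ff_bend_cpp(NumericVector rp, NumericVector rm, NumericVector rn, double k) {
  Vec3 a = v3(rp[0], rp[1], rp[2]), b = v3(rm[0], rm[1], rm[2]), c = v3(rn[0], rn[1], rn[2]);
  if (norm(a - b) <= 1e-12 || norm(b - c) <= 1e-12) stop("degenerate bending angle");
  double U; Vec3 Fp, Fm, Fn;
  bend_term(a, b, c, k, U, Fp, Fm, Fn);
  return List::create(_["energy"] = U,
                      _["force_prev"] = NumericVector::create(Fp.x, Fp.y, Fp.z),
                      _["force_mid"] = NumericVector::create(Fm.x, Fm.y, Fm.z),
                      _["force_next"] = NumericVector::create(Fn.x, Fn.y, Fn.z));
}

// [[Rcpp::export]]
List ff_align_cpp(NumericVector p, NumericMatrix bonds, double k, double theta0_deg) {
  if (norm(v3(p[0], p[1], p[2])) <= 1e-12) stop("zero polarization vector");
  double c0 = std::cos(theta0_deg * M_PI / 180.0);
  double U = 0; Vec3 gp = v3(0, 0, 0);
  NumericMatrix gB(bonds.nrow(), 3);
  for (int r = 0; r < bonds.nrow(); ++r) {
    Vec3 b = v3(bonds(r, 0), bonds(r, 1), bonds(r, 2));
    if (norm(b) <= 1e-12) stop("zero-length bond vector");
    double u; Vec3 g, gb;
    align_term(v3(p[0], p[1], p[2]), b, k, c0, u, g, gb);
    U += u; gp = gp + g;
    gB(r, 0) = gb.x; gB(r, 1) = gb.y; gB(r, 2) = gb.z;
  }
  Vec3 t = (-1.0) * cross(v3(p[0], p[1], p[2]), gp);
  return List::create(_["energy"] = U,
                      _["dUdp"] = NumericVector::create(gp.x, gp.y, gp.z),
                      _["torque"] = NumericVector::create(t.x, t.y, t.z),
                      _["dUdbond"] = gB);
}

// [[Rcpp::export]]
List ff_helix_cpp(NumericVector pi_, NumericVector pj_, double k, double psi_deg) {
  double U; Vec3 g1, g2;
  Vec3 pi = v3(pi_[0], pi_[1], pi_[2]), pj = v3(pj_[0], pj_[1], pj_[2]);
  helix_term(pi, pj, k, std::cos(psi_deg * M_PI / 180.0), U, g1, g2);
  Vec3 t1 = (-1.0) * cross(pi, g1), t2 = (-1.0) * cross(pj, g2);
  return List::create(_["energy"] = U,
                      _["dUdp_i"] = NumericVector::create(g1.x, g1.y, g1.z),
                      _["dUdp_j"] = NumericVector::create(g2.x, g2.y, g2.z),
                      _["torque_i"] = NumericVector::create(t1.x, t1.y, t1.z),
                      _["torque_j"] = NumericVector::create(t2.x, t2.y, t2.z));
}

// [[Rcpp::export]]
List compute_forces_cpp(NumericMatrix pos, NumericMatrix pol, IntegerVector species,
                        IntegerVector nuc, NumericVector alpha, LogicalVector anchored,
                        List chains, LogicalVector chainAnchored, IntegerMatrix xlinks,
                        double t, int n_para0, List ffl, int binding_mode,
                        bool use_pairlist) {
  Sys S = parse_sys(pos, pol, species, nuc, alpha, anchored, chains, chainAnchored,
                    xlinks, t, n_para0);
  for (int i = 0; i < S.N; ++i)
    if (!R_finite(S.px[i]) || !R_finite(S.py[i]) || !R_finite(S.pz[i]))
      stop("non-finite coordinate for subunit %d (integration blow-up?)", i + 1);
  FF ff = parse_ff(ffl);
  std::vector<char> bindable;
  compute_bindable(S, binding_mode, bindable);
  ForceOut out;
  std::vector<std::array<double, 3>> table;
  if (use_pairlist) {
    PairList pl;
    build_pairlist(S, ff, pl);
    compute_forces(S, ff, bindable, &pl, out, &table);
  } else {
    compute_forces(S, ff, bindable, nullptr, out, &table);
  }
  int N = S.N;
  NumericMatrix F(N, 3), TQ(N, 3);
  NumericVector mx(N), me(N);
  for (int i = 0; i < N; ++i) {
    F(i, 0) = out.fx[i]; F(i, 1) = out.fy[i]; F(i, 2) = out.fz[i];
    Vec3 tq = (-1.0) * cross(POL(S, i), v3(out.gx[i], out.gy[i], out.gz[i]));
    TQ(i, 0) = tq.x; TQ(i, 1) = tq.y; TQ(i, 2) = tq.z;
    mx[i] = out.maxbind[i]; me[i] = out.minE_parb[i];
  }
  NumericMatrix tab(table.size(), 3);
  for (size_t r = 0; r < table.size(); ++r) {
    tab(r, 0) = table[r][0]; tab(r, 1) = table[r][1]; tab(r, 2) = table[r][2];
  }
  colnames(tab) = CharacterVector::create("para_id", "parb_id", "energy");
  return List::create(_["forces"] = F, _["torques"] = TQ, _["energy"] = out.U,
                      _["max_binding"] = mx, _["min_pair_energy"] = me,
                      _["binding_pairs"] = tab);
}

// ---------------------------------------------------------------- chemistry

struct EventLog {
  std::vector<double> time;
  std::vector<int> kind, subunit, chain;
  void add(double t, int k, int s, int c) {
    time.push_back(t); kind.push_back(k); subunit.push_back(s + 1); chain.push_back(c + 1);
  }
};

static void chem_hydrolysis(Sys& S, const std::vector<double>& maxbind, double eps_threshold,
                            double k_h, double dt, RNG& rng, EventLog& ev) {
  if (k_h <= 0) return;
  double p = 1.0 - std::exp(-k_h * dt);
  for (int i = 0; i < S.N; ++i) {
    if (S.species[i] != SP_PARA || S.nuc[i] != NUC_ATP || S.chain_id[i] < 0) continue;
    if (maxbind[i] < eps_threshold) continue;
    if (rng.unif() < p) { S.nuc[i] = NUC_ADP; ev.add(S.t, EV_HYDROLYSIS, i, S.chain_id[i]); }
  }
}

static void remove_crosslinks_of(Sys& S, int id) {
  S.xl.erase(std::remove_if(S.xl.begin(), S.xl.end(),
                            [id](const std::array<int, 2>& x) { return x[0] == id || x[1] == id; }),
             S.xl.end());
}

static bool chem_depoly(Sys& S, double k_d, double dt, RNG& rng, EventLog& ev) {
  if (k_d <= 0) return false;
  double p = 1.0 - std::exp(-k_d * dt);
  bool changed = false;
  for (size_t c = 0; c < S.chains.size(); ++c) {
    std::vector<int>& ch = S.chains[c];
    if (ch.empty() || S.species[ch[0]] != SP_PARA) continue;
    // front tip
    int tip = ch.front();
    if (S.nuc[tip] == NUC_ADP && !S.anchored[tip] && rng.unif() < p) {
      ev.add(S.t, EV_DEPOLY, tip, (int)c);
      ch.erase(ch.begin());
      remove_crosslinks_of(S, tip);
      changed = true;
    }
    // back tip only when the chain was never anchored
    if (!S.chain_anchored[c] && ch.size() > 1) {
      int bt = ch.back();
      if (S.nuc[bt] == NUC_ADP && !S.anchored[bt] && rng.unif() < p) {
        ev.add(S.t, EV_DEPOLY, bt, (int)c);
        ch.pop_back();
        remove_crosslinks_of(S, bt);
        changed = true;
      }
    }
  }
  if (changed) {
    // drop empty chains
    std::vector<std::vector<int>> nc; std::vector<char> na;
    for (size_t c = 0; c < S.chains.size(); ++c)
      if (!S.chains[c].empty()) { nc.push_back(S.chains[c]); na.push_back(S.chain_anchored[c]); }
    S.chains = nc; S.chain_anchored = na;
    reindex_chains(S);
  }
  return changed;
}

static bool chem_sever(Sys& S, double k_d, double dt, RNG& rng, EventLog& ev) {
  if (k_d <= 0) return false;
  double p = 1.0 - std::exp(-k_d * dt);
  bool changed = false;
  std::vector<std::vector<int>> newChains; std::vector<char> newAnch;
  for (size_t c = 0; c < S.chains.size(); ++c) {
    std::vector<int>& ch = S.chains[c];
    bool isA = !ch.empty() && S.species[ch[0]] == SP_PARA;
    std::vector<int> cuts;
    if (isA) {
      for (size_t k = 1; k + 1 < ch.size(); ++k)
        if (S.nuc[ch[k]] == NUC_ADP && !S.anchored[ch[k]] && rng.unif() < p) cuts.push_back((int)k);
    }
    if (cuts.empty()) { newChains.push_back(ch); newAnch.push_back(S.chain_anchored[c]); continue; }
    changed = true;
    size_t start = 0;
    for (int cut : cuts) {
      ev.add(S.t, EV_SEVER, ch[cut], (int)c);
      remove_crosslinks_of(S, ch[cut]); // severed subunit becomes a free monomer
      if ((size_t)cut > start) {
        std::vector<int> seg(ch.begin() + start, ch.begin() + cut);
        newChains.push_back(seg); newAnch.push_back(0); // tip-side fragments unanchored
      }
      start = cut + 1;
    }
    if (start < ch.size()) {
      std::vector<int> seg(ch.begin() + start, ch.end());
      newChains.push_back(seg);
      newAnch.push_back(S.chain_anchored[c]); // anchor-side run keeps its anchoring
    }
  }
  if (changed) { S.chains = newChains; S.chain_anchored = newAnch; reindex_chains(S); }
  return changed;
}

// standalone chemistry steps for unit testing -------------------------------

// [[Rcpp::export]]
List chem_step_cpp(NumericMatrix pos, NumericMatrix pol, IntegerVector species,
                   IntegerVector nuc, NumericVector alpha, LogicalVector anchored,
                   List chains, LogicalVector chainAnchored, IntegerMatrix xlinks,
                   double t, int n_para0, std::string what, NumericVector maxbind,
                   double eps_threshold, double k_h, double k_d, double dt, int seed) {
  Sys S = parse_sys(pos, pol, species, nuc, alpha, anchored, chains, chainAnchored,
                    xlinks, t, n_para0);
  RNG rng((uint64_t)seed);
  EventLog ev;
  if (what == "hydrolysis") {
    std::vector<double> mb(maxbind.begin(), maxbind.end());
    chem_hydrolysis(S, mb, eps_threshold, k_h, dt, rng, ev);
  } else if (what == "depolymerization") {
    chem_depoly(S, k_d, dt, rng, ev);
  } else if (what == "severing") {
    chem_sever(S, k_d, dt, rng, ev);
  } else stop("unknown chemistry step '%s'", what.c_str());
  List outChains(S.chains.size());
  LogicalVector outAnch(S.chains.size());
  for (size_t c = 0; c < S.chains.size(); ++c) {
    IntegerVector v(S.chains[c].size());
    for (size_t k = 0; k < S.chains[c].size(); ++k) v[k] = S.chains[c][k] + 1;
    outChains[c] = v; outAnch[c] = S.chain_anchored[c] != 0;
  }
  IntegerMatrix oxl(S.xl.size(), 2);
  for (size_t m = 0; m < S.xl.size(); ++m) { oxl(m, 0) = S.xl[m][0] + 1; oxl(m, 1) = S.xl[m][1] + 1; }
  IntegerVector onuc(S.N);
  for (int i = 0; i < S.N; ++i) onuc[i] = S.nuc[i];
  return List::create(_["nucleotide"] = onuc, _["chains"] = outChains,
                      _["chain_anchored"] = outAnch, _["crosslinks"] = oxl,
                      _["events"] = DataFrame::create(_["time"] = ev.time, _["kind"] = ev.kind,
                                                      _["subunit_id"] = ev.subunit,
                                                      _["filament_id"] = ev.chain));
}

// ---------------------------------------------------------------- main loop

// [[Rcpp::export]]
List run_core_cpp(NumericMatrix pos, NumericMatrix pol, IntegerVector species,
                  IntegerVector nuc, NumericVector alpha, LogicalVector anchored,
                  List chains, LogicalVector chainAnchored, IntegerMatrix xlinks,
                  double t0, int n_para0, List ffl, List cheml, List integl,
                  Nullable<NumericMatrix> ext_force, IntegerVector track_ids,
                  bool use_pairlist, int frame_stride) {
  Sys S = parse_sys(pos, pol, species, nuc, alpha, anchored,
                    chains, chainAnchored, xlinks, t0, n_para0);
  FF ff = parse_ff(ffl);

  double k_h = as<double>(cheml["k_h"]);
  double k_d = as<double>(cheml["k_d"]);
  double eps_thr = as<double>(cheml["eps_threshold"]);
  int binding_mode = as<int>(cheml["binding_mode_code"]);
  int disassembly_mode = as<int>(cheml["disassembly_mode_code"]);
  bool chem_on = as<bool>(cheml["chemistry_on"]);
  double cull_dist = cheml.containsElementNamed("remove_monomer_distance") &&
                     !Rf_isNull(cheml["remove_monomer_distance"]) ?
                     as<double>(cheml["remove_monomer_distance"]) : -1.0;

  double dt = as<double>(integl["dt"]);
  double kT = as<double>(integl["kT"]);
  double gamma0 = as<double>(integl["gamma0"]);
  double gamma_rot = as<double>(integl["gamma_rot"]);
  long n_steps = (long)as<double>(integl["n_steps"]);
  int seed = as<int>(integl["seed"]);
  int sample_stride = as<int>(integl["sample_stride"]);
  double bound_cut = as<double>(integl["bound_cut"]);

  RNG rng((uint64_t)seed);

  bool has_ext = ext_force.isNotNull();
  NumericMatrix extF;
  if (has_ext) extF = NumericMatrix(ext_force);

  std::vector<char> bindable;
  compute_bindable(S, binding_mode, bindable);
  PairList pl;
  ForceOut fo;
  EventLog ev;
  std::vector<char> culled(S.N, 0);
  long n_culled = 0;

  int n_samp = sample_stride > 0 ? (int)(n_steps / sample_stride) : 0;
  const int NCOL = 23;
  NumericMatrix samples(n_samp, NCOL);
  NumericMatrix track(n_samp, 3 * track_ids.size());
  List frames(frame_stride > 0 ? (int)(n_steps / frame_stride) : 0);
  int isamp = 0, iframe = 0;
  long cum_h = 0, cum_d = 0, cum_s = 0;
  double maxdisp = 0;
  long n_capped = 0;

  // stability precondition: the stiffest harmonic term must relax over
  // several steps (dt << gamma0 a^2 / kT scaled by the spring constants)
  double kmaxstiff = std::max(ff.k_bond, std::max(ff.k_crosslink, ff.k_wall));
  if (kmaxstiff * dt / gamma0 > 0.5)
    Rcpp::warning("dt violates the stability precondition (k_max*dt/gamma0 = %.2f > 0.5)",
                  kmaxstiff * dt / gamma0);

  for (long step = 0; step < n_steps; ++step) {
    if (use_pairlist) {
      if (pairlist_stale(S, pl)) build_pairlist(S, ff, pl);
      compute_forces(S, ff, bindable, &pl, fo, nullptr);
    } else {
      compute_forces(S, ff, bindable, nullptr, fo, nullptr);
    }
    if (has_ext)
      for (int i = 0; i < S.N; ++i) {
        fo.fx[i] += extF(i, 0); fo.fy[i] += extF(i, 1); fo.fz[i] += extF(i, 2);
      }

    // positions
    for (int i = 0; i < S.N; ++i) {
      if (S.anchored[i] || culled[i]) continue;
      double mob = dt / (S.alpha[i] * gamma0);
      double sd = std::sqrt(2.0 * kT * mob);
      double dx = fo.fx[i] * mob, dy = fo.fy[i] * mob, dz = fo.fz[i] * mob;
      if (kT > 0) { dx += sd * rng.normal(); dy += sd * rng.normal(); dz += sd * rng.normal(); }
      double d2 = dx * dx + dy * dy + dz * dz;
      // displacement cap: keeps the first-order update stable through the
      // steep WCA core when subunits are driven into deep overlap
      double cap = 0.25 * ff.a;
      if (d2 > cap * cap) {
        double sc = cap / std::sqrt(d2);
        dx *= sc; dy *= sc; dz *= sc;
        d2 = cap * cap;
        ++n_capped;
      }
      if (d2 > maxdisp) maxdisp = d2;
      S.px[i] += dx; S.py[i] += dy; S.pz[i] += dz;
      if (!R_finite(S.px[i])) stop("NaN position for subunit %d at step %ld", i + 1, step);
    }
    // polarizations: rotate by Omega = T dt / gamma_rot + thermal rotation
    double sdr = kT > 0 ? std::sqrt(2.0 * kT * dt / gamma_rot) : 0.0;
    for (int i = 0; i < S.N; ++i) {
      if (S.anchored[i] || culled[i]) continue;
      Vec3 p = POL(S, i);
      Vec3 T = (-1.0) * cross(p, v3(fo.gx[i], fo.gy[i], fo.gz[i]));
      Vec3 Om = (dt / gamma_rot) * T;
      if (sdr > 0) Om = Om + v3(sdr * rng.normal(), sdr * rng.normal(), sdr * rng.normal());
      double th = norm(Om);
      if (th > 1e-14) {
        Vec3 ax = (1.0 / th) * Om;
        double ct = std::cos(th), st = std::sin(th);
        Vec3 pn = ct * p + st * cross(ax, p) + ((1 - ct) * dot(ax, p)) * ax;
        double nn = norm(pn);
        S.ux[i] = pn.x / nn; S.uy[i] = pn.y / nn; S.uz[i] = pn.z / nn;
      }
    }
    S.t += dt;

    // chemistry (per-step Bernoulli conversions)
    if (chem_on) {
      size_t nev = ev.time.size();
      chem_hydrolysis(S, fo.maxbind, eps_thr, k_h, dt, rng, ev);
      bool topo = chem_depoly(S, k_d, dt, rng, ev);
      if (disassembly_mode == 1) topo = chem_sever(S, k_d, dt, rng, ev) || topo;
      if (topo) pl.valid = false; // 1-2 exclusions follow the topology
      if (ev.time.size() != nev || topo) {
        compute_bindable(S, binding_mode, bindable);
        for (size_t e = nev; e < ev.time.size(); ++e) {
          if (ev.kind[e] == EV_HYDROLYSIS) ++cum_h;
          else if (ev.kind[e] == EV_DEPOLY) ++cum_d;
          else ++cum_s;
        }
      }
      if (cull_dist > 0 && (step % 200) == 199) {
        for (int i = 0; i < S.N; ++i) {
          if (culled[i] || S.species[i] != SP_PARA || S.chain_id[i] >= 0) continue;
          double best = 1e30;
          for (int j = 0; j < S.N; ++j) {
            if (j == i || culled[j] || (S.species[j] == SP_PARA && S.chain_id[j] < 0)) continue;
            double dx = S.px[i] - S.px[j], dy = S.py[i] - S.py[j], dz = S.pz[i] - S.pz[j];
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < best) best = d2;
          }
          if (best > cull_dist * cull_dist) {
            culled[i] = 1; ++n_culled;
            // park it far away so it never re-enters pair lists
            S.px[i] = 1e6 + i; S.py[i] = 1e6; S.pz[i] = 1e6;
          }
        }
      }
    }

    // sampling
    if (sample_stride > 0 && (step + 1) % sample_stride == 0 && isamp < n_samp) {
      double pbx = 0, pby = 0, pbz = 0; int nb = 0;
      double pax = 0, pay = 0, paz = 0; int na = 0;
      for (int i = 0; i < S.N; ++i) {
        if (S.species[i] != SP_PARA) { pbx += S.px[i]; pby += S.py[i]; pbz += S.pz[i]; ++nb; }
        else if (S.chain_id[i] >= 0) { pax += S.px[i]; pay += S.py[i]; paz += S.pz[i]; ++na; }
      }
      if (nb) { pbx /= nb; pby /= nb; pbz /= nb; }
      if (na) { pax /= na; pay /= na; paz /= na; }
      double gxx = 0, gyy = 0, gzz = 0, gxy = 0, gxz = 0, gyz = 0;
      for (int i = 0; i < S.N; ++i) {
        if (S.species[i] == SP_PARA) continue;
        double dx = S.px[i] - pbx, dy = S.py[i] - pby, dz = S.pz[i] - pbz;
        gxx += dx * dx; gyy += dy * dy; gzz += dz * dz;
        gxy += dx * dy; gxz += dx * dz; gyz += dy * dz;
      }
      if (nb) { gxx /= nb; gyy /= nb; gzz /= nb; gxy /= nb; gxz /= nb; gyz /= nb; }
      int nbound = 0, nbound_anch = 0;
      bool anyAnchA = false;
      for (size_t c = 0; c < S.chains.size(); ++c)
        if (S.chain_anchored[c] && S.chains[c].size() >= 2 &&
            S.species[S.chains[c][0]] == SP_PARA) anyAnchA = true;
      std::vector<double> bx;
      for (int i = 0; i < S.N; ++i)
        if (S.species[i] == SP_PARB_BIND && fo.minE_parb[i] <= -bound_cut) {
          ++nbound; bx.push_back(S.px[i]);
          // bound to the anchored main bundle (all chains when unanchored)
          if (!anyAnchA || fo.minE_parb_anch[i] <= -bound_cut) ++nbound_anch;
        }
      // mean free-tip x over anchored ParA chains (all ParA chains if none anchored)
      double tipx = 0; int ntip = 0;
      for (size_t c = 0; c < S.chains.size(); ++c) {
        if (S.chains[c].empty() || S.species[S.chains[c][0]] != SP_PARA) continue;
        if (anyAnchA && !(S.chain_anchored[c] && S.chains[c].size() >= 2)) continue;
        tipx += S.px[S.chains[c].front()]; ++ntip;
      }
      if (ntip) tipx /= ntip;
      double delta = 0;
      if (!bx.empty()) {
        std::sort(bx.begin(), bx.end());
        double q = 0.9 * (bx.size() - 1);
        int lo = (int)std::floor(q);
        double frac = q - lo;
        double xq = bx[lo] + frac * (bx[std::min((int)bx.size() - 1, lo + 1)] - bx[lo]);
        delta = std::max(0.0, xq - tipx);
      }
      int nfil = 0;
      for (size_t c = 0; c < S.chains.size(); ++c)
        if (S.chains[c].size() >= 2 && S.species[S.chains[c][0]] == SP_PARA) ++nfil;
      // distance from the ParB COM to the anchored main bundle (all
      // polymerized ParA when nothing is anchored)
      double dmin = 1e30;
      for (int i = 0; i < S.N; ++i) {
        if (S.species[i] != SP_PARA || S.chain_id[i] < 0) continue;
        if (anyAnchA && !(S.chain_anchored[S.chain_id[i]] &&
                          S.chains[S.chain_id[i]].size() >= 2)) continue;
        double dx = S.px[i] - pbx, dy = S.py[i] - pby, dz = S.pz[i] - pbz;
        double d2 = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d2 < dmin) dmin = d2;
      }
      if (dmin > 1e29) dmin = NA_REAL;
      double row[NCOL] = {S.t, pbx, pby, pbz, pax, pay, paz,
                          gxx, gyy, gzz, gxy, gxz, gyz,
                          (double)nbound, (double)nbound_anch, delta, tipx,
                          (double)na, (double)nfil,
                          dmin, (double)cum_h, (double)cum_d, (double)cum_s};
      for (int c2 = 0; c2 < NCOL; ++c2) samples(isamp, c2) = row[c2];
      for (int k = 0; k < track_ids.size(); ++k) {
        int id = track_ids[k] - 1;
        track(isamp, 3 * k) = S.px[id];
        track(isamp, 3 * k + 1) = S.py[id];
        track(isamp, 3 * k + 2) = S.pz[id];
      }
      ++isamp;
    }
    if (frame_stride > 0 && (step + 1) % frame_stride == 0 && iframe < frames.size()) {
      NumericMatrix fp(S.N, 3), fq(S.N, 3);
      IntegerVector fn(S.N), fc(S.N), fk(S.N);
      for (int i = 0; i < S.N; ++i) {
        fp(i, 0) = S.px[i]; fp(i, 1) = S.py[i]; fp(i, 2) = S.pz[i];
        fq(i, 0) = S.ux[i]; fq(i, 1) = S.uy[i]; fq(i, 2) = S.uz[i];
        fn[i] = S.nuc[i]; fc[i] = S.chain_id[i] + 1; // 0 = monomer
        fk[i] = S.chain_idx[i] + 1;
      }
      frames[iframe++] = List::create(_["time"] = S.t, _["pos"] = fp, _["pol"] = fq,
                                      _["nucleotide"] = fn, _["chain_id"] = fc,
                                      _["chain_index"] = fk);
    }
    if ((step & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  // stability audit: sustained displacement capping means dt is too coarse
  // for the configured stiffnesses
  if (n_capped > (long)(1e-2 * (double)S.N * (double)n_steps))
    Rcpp::warning("%.2f%% of particle updates hit the displacement cap; consider a smaller dt",
                  100.0 * (double)n_capped / ((double)S.N * (double)n_steps));

  colnames(samples) = CharacterVector::create(
      "time", "parb_x", "parb_y", "parb_z", "para_x", "para_y", "para_z",
      "g_xx", "g_yy", "g_zz", "g_xy", "g_xz", "g_yz",
      "n_bound", "n_bound_anchored", "delta", "tip_x", "n_poly", "n_filaments",
      "dmin_com", "cum_hydrolysis", "cum_depoly", "cum_sever");

  NumericMatrix opos(S.N, 3), opol(S.N, 3);
  IntegerVector onuc(S.N);
  LogicalVector ocul(S.N);
  for (int i = 0; i < S.N; ++i) {
    opos(i, 0) = S.px[i]; opos(i, 1) = S.py[i]; opos(i, 2) = S.pz[i];
    opol(i, 0) = S.ux[i]; opol(i, 1) = S.uy[i]; opol(i, 2) = S.uz[i];
    onuc[i] = S.nuc[i]; ocul[i] = culled[i] != 0;
  }
  List outChains(S.chains.size());
  LogicalVector outAnch(S.chains.size());
  for (size_t c = 0; c < S.chains.size(); ++c) {
    IntegerVector v(S.chains[c].size());
    for (size_t k = 0; k < S.chains[c].size(); ++k) v[k] = S.chains[c][k] + 1;
    outChains[c] = v; outAnch[c] = S.chain_anchored[c] != 0;
  }
  IntegerMatrix oxl(S.xl.size(), 2);
  for (size_t m = 0; m < S.xl.size(); ++m) { oxl(m, 0) = S.xl[m][0] + 1; oxl(m, 1) = S.xl[m][1] + 1; }

  return List::create(
      _["pos"] = opos, _["pol"] = opol, _["nucleotide"] = onuc,
      _["chains"] = outChains, _["chain_anchored"] = outAnch, _["crosslinks"] = oxl,
      _["time"] = S.t, _["culled"] = ocul,
      _["samples"] = samples, _["track"] = track, _["frames"] = frames,
      _["events"] = DataFrame::create(_["time"] = ev.time, _["kind"] = ev.kind,
                                      _["subunit_id"] = ev.subunit, _["filament_id"] = ev.chain),
      _["max_step_displacement"] = std::sqrt(maxdisp),
      _["n_capped"] = (double)n_capped,
      _["n_culled"] = (double)n_culled);
}

// ----------------------------------------------------------- misc utilities

// minimum binding energy over n random pair geometries (boundedness scan)
// [[Rcpp::export]]
double binding_min_scan_cpp(int n, int seed, List ffl) {
  FF ff = parse_ff(ffl);
  RNG rng((uint64_t)seed);
  auto runit = [&]() {
    for (;;) {
      Vec3 v = v3(2 * rng.unif() - 1, 2 * rng.unif() - 1, 2 * rng.unif() - 1);
      double n2 = dot(v, v);
      if (n2 > 1e-6 && n2 <= 1.0) return (1.0 / std::sqrt(n2)) * v;
    }
  };
  double emin = 0;
  for (int i = 0; i < n; ++i) {
    double r = 0.3 + 1.4 * rng.unif();
    Vec3 rj = r * runit();
    double U; Vec3 Fj, g1, g2;
    binding_term(v3(0, 0, 0), rj, runit(), runit(), ff, U, Fj, g1, g2);
    if (U < emin) emin = U;
  }
  return emin;
}

// deterministic Gaussian stream (thermal-kick sampler)
// [[Rcpp::export]]
NumericVector gauss_stream_cpp(int n, double variance, int seed) {
  if (variance < 0) stop("variance must be >= 0");
  NumericVector out(n);
  if (variance == 0) return out;
  RNG rng((uint64_t)seed);
  double sdv = std::sqrt(variance);
  for (int i = 0; i < n; ++i) out[i] = sdv * rng.normal();
  return out;
}

// Brute-force 1D overdamped first-passage times in a tabulated potential.
// Particle starts at x_start; absorbed at x <= x_abs; reflected at the grid's
// right edge.  Force is the negative slope of the piecewise-linear potential.
// [[Rcpp::export]]
NumericVector mfpt1d_cpp(NumericVector xgrid, NumericVector U, double gamma_,
                         double kT, double x_start, double x_abs, double dt,
                         int n_rep, double max_time, int seed) {
  int n = xgrid.size();
  double x0 = xgrid[0], h = xgrid[1] - xgrid[0], xmax = xgrid[n - 1];
  std::vector<double> F(n - 1);
  for (int i = 0; i + 1 < n; ++i) F[i] = -(U[i + 1] - U[i]) / h;
  RNG rng((uint64_t)seed);
  double mob = dt / gamma_, sd = std::sqrt(2.0 * kT * mob);
  long max_steps = (long)(max_time / dt);
  NumericVector out(n_rep);
  for (int r = 0; r < n_rep; ++r) {
    double x = x_start, t = 0;
    long s = 0;
    for (; s < max_steps; ++s) {
      int bin = (int)((x - x0) / h);
      if (bin < 0) bin = 0;
      if (bin > n - 2) bin = n - 2;
      x += F[bin] * mob + sd * rng.normal();
      if (x > xmax) x = 2 * xmax - x;
      t += dt;
      if (x <= x_abs) break;
    }
    out[r] = (s >= max_steps) ? NA_REAL : t;
    Rcpp::checkUserInterrupt();
  }
  return out;
}
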