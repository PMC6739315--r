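// Particle-world engine: Brownian motion in spherical compartments,
// encounter-driven reaction rules along the integrin-FAK-Ras-Raf-MEK-ERK
// chain, Runx2-driven transcription/translation, matrix-protein secretion,
// and the per-second coupling to the closed-form interface mechanics.
//
// All randomness flows through four independent xoshiro256++ streams
// (motion, reactions, expression, basal) seeded deterministically from the
// run seed, so a run is bit-reproducible and toggling one mechanism does
// not perturb the draws of another.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----

struct Xoshiro {
  uint64_t s[4];
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

static uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static void seed_stream(Xoshiro &st, int seed, int stream) {
  uint64_t x = (uint64_t)(uint32_t)seed ^ (0xA0761D6478BD642FULL * (uint64_t)(stream + 1));
  for (int i = 0; i < 4; i++) st.s[i] = splitmix64(x);
  for (int i = 0; i < 8; i++) st.next();  // warm up
}

// ziggurat normal generator (Marsaglia & Tsang), deterministic tables
static uint32_t zig_kn[128];
static double zig_wn[128], zig_fn[128];
static bool zig_ready = false;

static void zig_setup() {
  double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3,
         m1 = 2147483648.0;
  double q = vn / std::exp(-0.5 * dn * dn);
  zig_kn[0] = (uint32_t)((dn / q) * m1);
  zig_kn[1] = 0;
  zig_wn[0] = q / m1;
  zig_wn[127] = dn / m1;
  zig_fn[0] = 1.0;
  zig_fn[127] = std::exp(-0.5 * dn * dn);
  for (int i = 126; i >= 1; i--) {
    dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
    zig_kn[i + 1] = (uint32_t)((dn / tn) * m1);
    tn = dn;
    zig_fn[i] = std::exp(-0.5 * dn * dn);
    zig_wn[i] = dn / m1;
  }
  zig_ready = true;
}

static double zig_norm(Xoshiro &rng) {
  const double r = 3.442619855899, rinv = 0.2904764517;
  for (;;) {
    uint64_t u = rng.next();
    int32_t hz = (int32_t)(uint32_t)u;
    uint32_t iz = (uint32_t)u & 127u;
    uint32_t ahz = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
    if (ahz < zig_kn[iz]) return hz * zig_wn[iz];
    // edge handling
    for (;;) {
      double x;
      if (iz == 0) {
        double y;
        do {
          x = -std::log(rng.unif()) * rinv;
          y = -std::log(rng.unif());
        } while (y + y < x * x);
        return (hz > 0) ? r + x : -r - x;
      }
      x = hz * zig_wn[iz];
      if (zig_fn[iz] + rng.unif() * (zig_fn[iz - 1] - zig_fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
      u = rng.next();
      hz = (int32_t)(uint32_t)u;
      iz = (uint32_t)u & 127u;
      ahz = hz < 0 ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
      if (ahz < zig_kn[iz]) return hz * zig_wn[iz];
    }
  }
}

static int zig_pois(Xoshiro &rng, double lambda) {
  // inversion; lambda is small (<< 10) in this model
  double L = std::exp(-lambda), p = 1.0;
  int k = 0;
  do { k++; p *= rng.unif(); } while (p > L);
  return k - 1;
}

// pack/unpack stream states to an R integer vector (8 ints per stream)
static void rng_unpack(const IntegerVector &v, Xoshiro st[4]) {
  for (int k = 0; k < 4; k++)
    std::memcpy(st[k].s, &v[k * 8], 4 * sizeof(uint64_t));
}
static void rng_pack(IntegerVector &v, const Xoshiro st[4]) {
  for (int k = 0; k < 4; k++)
    std::memcpy(&v[k * 8], st[k].s, 4 * sizeof(uint64_t));
}

// [[Rcpp::export]]
IntegerVector rng_state_init(int seed) {
  Xoshiro st[4];
  for (int k = 0; k < 4; k++) seed_stream(st[k], seed, k);
  IntegerVector v(32);
  rng_pack(v, st);
  return v;
}

// ------------------------------------------------------------ species ----

enum Species { SP_INTEGRIN = 0, SP_FAK, SP_RAS, SP_RAF, SP_MEK, SP_ERK,
               SP_RUNX2, SP_COMPLEX, SP_RIBOSOME, SP_MRNA, SP_PROTEIN };
enum State { ST_DEAD = -1, ST_BASAL = 0, ST_ACTIVE = 1, ST_REFRACTORY = 2,
             ST_TRANSCRIBING = 3, ST_INTERMEDIATE = 4, ST_INERT = 5 };

// kinetics vector layout; must match names(kinetics_params()) in R
enum Kin {
  K_PRIME_MEAN = 0, K_OFF_DELAY,
  K_R_IF, K_P_IF, K_ACS_INTEGRIN,
  K_R_FR, K_P_FR, K_ACS_FAK,
  K_R_RR, K_P_RR, K_ACS_RAS,
  K_R_RM, K_P_RM, K_ACS_RAF,
  K_R_ME, K_P_ME, K_ACS_MEK,
  K_R_EX, K_P_EX, K_ACS_ERK,
  K_R_XC, K_P_XC, K_ACS_RUNX2,
  K_R_TR, K_P_TR,
  K_LIFE_FAK, K_LIFE_RAS, K_LIFE_RAF, K_LIFE_MEK, K_LIFE_ERK,
  K_LIFE_INTER, K_LIFE_RASINT, K_LIFE_RUNX2, K_LIFE_RELW, K_LIFE_DIST,
  K_LIFE_CAP,
  K_POST_FAK, K_POST_RAS, K_POST_RAF, K_POST_MEK, K_POST_ERK, K_POST_RUNX2,
  K_BASAL_RATE, K_BASAL_LO, K_BASAL_HI,
  K_TX_LO, K_TX_HI, K_ACS_COMPLEX,
  K_YIELD_MEAN, K_YIELD_SD,
  K_ACS_MRNA, K_ACS_RIBOSOME,
  K_MRNA_LIFETIME, K_SECRETION_DELAY,
  K_D_KINASE, K_D_MRNA, K_D_RIBOSOME, K_D_PROTEIN, K_D_NUCLEAR,
  K_GENE_W0, K_GENE_W1, K_GENE_W2, K_GENE_W3,
  K_N_PARAMS
};

// mechanics vector layout (see R .mech_flat)
enum Mech { M_ETA0 = 0, M_K0, M_FSCALE, M_INCREMENT, M_BETA, M_CONV,
            M_SIGMA_ON, M_RCELL, M_RNUC, M_MU_BASE, M_N_PARAMS };

// [[Rcpp::export]]
int kinetics_n_params() { return K_N_PARAMS; }

static double stress_coef(double eta, double k) {
  return 5.0 * eta * k /
         (6.0 * (2.0 * eta + k) +
          4.0 * eta * k * (71.0 * eta + 16.0 * k) /
              (152.0 * eta + 19.0 * eta * k + 16.0 * k));
}

// force factor (relative to the unstiffened state) for modulus multiplier m
static double force_factor(double eta0, double k0, double m) {
  return stress_coef(eta0 / m, k0 / m) / stress_coef(eta0, k0);
}

static double modulus_multiplier(double n_dep, double inc, double beta,
                                 int conv) {
  if (conv == 1) return std::pow(1.0 + inc, n_dep);      // compound
  return std::pow(1.0 + inc * n_dep, beta);              // power / linear
}

// --------------------------------------------------------------- world ----

struct World {
  std::vector<int> species, state, gene;
  std::vector<double> x, y, z, acs, life, aux;
  std::vector<int> freelist;
  int n_integrin;
  std::vector<double> mt, Xpat;  // per integrin
  double time_step;
  double n_dep;
  double dep_gene[4], cum_tx[4], cum_tl[4];
  Xoshiro rng[4];  // motion, reactions, expression, basal

  int n() const { return (int)species.size(); }

  int spawn(int sp, int st_, double px, double py, double pz, int g,
            double acs_, double life_, double aux_) {
    int id;
    if (!freelist.empty()) { id = freelist.back(); freelist.pop_back(); }
    else {
      species.push_back(0); state.push_back(0); gene.push_back(-1);
      x.push_back(0); y.push_back(0); z.push_back(0);
      acs.push_back(0); life.push_back(0); aux.push_back(0);
      id = (int)species.size() - 1;
    }
    species[id] = sp; state[id] = st_; gene[id] = g;
    x[id] = px; y[id] = py; z[id] = pz;
    acs[id] = acs_; life[id] = life_; aux[id] = aux_;
    return id;
  }
  void kill(int id) { state[id] = ST_DEAD; species[id] = -1; freelist.push_back(id); }
};

static World world_from_list(const List &w) {
  World W;
  IntegerVector sp = w["species"], st = w["state"], gn = w["gene"],
                fl = w["freelist"];
  NumericVector x = w["x"], y = w["y"], z = w["z"], acs = w["acs"],
                life = w["life"], aux = w["aux"], mt = w["mt"],
                Xp = w["Xpat"], dg = w["dep_gene"], ctx = w["cum_tx"],
                ctl = w["cum_tl"];
  W.species.assign(sp.begin(), sp.end());
  W.state.assign(st.begin(), st.end());
  W.gene.assign(gn.begin(), gn.end());
  W.freelist.assign(fl.begin(), fl.end());
  W.x.assign(x.begin(), x.end()); W.y.assign(y.begin(), y.end());
  W.z.assign(z.begin(), z.end());
  W.acs.assign(acs.begin(), acs.end());
  W.life.assign(life.begin(), life.end());
  W.aux.assign(aux.begin(), aux.end());
  W.mt.assign(mt.begin(), mt.end());
  W.Xpat.assign(Xp.begin(), Xp.end());
  W.n_integrin = as<int>(w["n_integrin"]);
  W.time_step = as<double>(w["time_step"]);
  W.n_dep = as<double>(w["n_dep"]);
  for (int g = 0; g < 4; g++) {
    W.dep_gene[g] = dg[g]; W.cum_tx[g] = ctx[g]; W.cum_tl[g] = ctl[g];
  }
  IntegerVector rv = w["rng"];
  rng_unpack(rv, W.rng);
  return W;
}

static List world_to_list(const World &W) {
  IntegerVector rv(32);
  rng_pack(rv, W.rng);
  return List::create(
      _["species"] = IntegerVector(W.species.begin(), W.species.end()),
      _["state"] = IntegerVector(W.state.begin(), W.state.end()),
      _["gene"] = IntegerVector(W.gene.begin(), W.gene.end()),
      _["x"] = NumericVector(W.x.begin(), W.x.end()),
      _["y"] = NumericVector(W.y.begin(), W.y.end()),
      _["z"] = NumericVector(W.z.begin(), W.z.end()),
      _["acs"] = NumericVector(W.acs.begin(), W.acs.end()),
      _["life"] = NumericVector(W.life.begin(), W.life.end()),
      _["aux"] = NumericVector(W.aux.begin(), W.aux.end()),
      _["freelist"] = IntegerVector(W.freelist.begin(), W.freelist.end()),
      _["mt"] = NumericVector(W.mt.begin(), W.mt.end()),
      _["Xpat"] = NumericVector(W.Xpat.begin(), W.Xpat.end()),
      _["n_integrin"] = W.n_integrin,
      _["time_step"] = W.time_step,
      _["n_dep"] = W.n_dep,
      _["dep_gene"] = NumericVector(W.dep_gene, W.dep_gene + 4),
      _["cum_tx"] = NumericVector(W.cum_tx, W.cum_tx + 4),
      _["cum_tl"] = NumericVector(W.cum_tl, W.cum_tl + 4),
      _["rng"] = rv);
}

// ---------------------------------------------------------------- grid ----

struct Grid {
  double cell, origin;
  int dim;
  std::vector<int> head, stamp, nxt;
  int cur;
  void init(double rcell, double cell_size, int capacity) {
    cell = cell_size;
    origin = -rcell - cell;
    dim = (int)std::ceil((2.0 * rcell + 2.0 * cell) / cell) + 1;
    head.assign((size_t)dim * dim * dim, -1);
    stamp.assign((size_t)dim * dim * dim, -1);
    nxt.assign(capacity, -1);
    cur = 0;
  }
  inline int idx3(double px, double py, double pz) const {
    int ix = (int)((px - origin) / cell), iy = (int)((py - origin) / cell),
        iz = (int)((pz - origin) / cell);
    return (ix * dim + iy) * dim + iz;
  }
  void tick() { cur++; }
  void insert(int id, double px, double py, double pz) {
    if ((int)nxt.size() <= id) nxt.resize(id + 256, -1);
    int c = idx3(px, py, pz);
    if (stamp[c] != cur) { stamp[c] = cur; head[c] = -1; }
    nxt[id] = head[c];
    head[c] = id;
  }
};

// ----------------------------------------------------------- main step ----

struct Ctx {
  const double *kin, *mech;
  double rcell, rnuc, rc2, rn2;
  bool reverse;
};

static inline double life_draw_u(Xoshiro &rng, double mean, double relw) {
  return mean * (1.0 - relw + 2.0 * relw * rng.unif());
}

static inline double life_draw(Xoshiro &rng, double mean, double relw,
                               int dist, double cap) {
  if (dist == 1) {
    // exponential truncated at cap * mean (bounds the longest-lived agents)
    double f = 1.0 - std::exp(-cap);
    return -mean * std::log(1.0 - rng.unif() * f);
  }
  return life_draw_u(rng, mean, relw);
}

// reflect position radially into [lo, hi]; lo = 0 disables inner bound
static inline void reflect(double &px, double &py, double &pz,
                           double lo, double hi) {
  double r2 = px * px + py * py + pz * pz;
  double hi2 = hi * hi, lo2 = lo * lo;
  if (r2 <= hi2 && r2 >= lo2) return;
  double r = std::sqrt(r2);
  if (r < 1e-9) { px = (lo + hi) / 2; py = 0; pz = 0; return; }
  double rt = r;
  if (r > hi) rt = 2.0 * hi - r;
  else if (lo > 0 && r < lo) rt = 2.0 * lo - r;
  if (rt > hi || rt < lo || rt <= 0)  // pathological double bounce
    rt = 0.5 * (lo + hi);
  double f = rt / r;
  px *= f; py *= f; pz *= f;
}

// nearest eligible substrate of species `sp` with state in {stA, stB}
static int find_substrate(const World &W, const Grid &G, const Ctx &C,
                          const std::vector<char> &used,
                          double px, double py, double pz, double radius,
                          int sp, int stA, int stB, bool need_cyt) {
  int span = (int)std::ceil(radius / G.cell);
  int ix = (int)((px - G.origin) / G.cell), iy = (int)((py - G.origin) / G.cell),
      iz = (int)((pz - G.origin) / G.cell);
  double best = radius * radius;
  int best_id = -1;
  for (int dx = -span; dx <= span; dx++)
    for (int dy = -span; dy <= span; dy++)
      for (int dz = -span; dz <= span; dz++) {
        int cx = ix + dx, cy = iy + dy, cz = iz + dz;
        if (cx < 0 || cy < 0 || cz < 0 || cx >= G.dim || cy >= G.dim ||
            cz >= G.dim)
          continue;
        int c = (cx * G.dim + cy) * G.dim + cz;
        if (G.stamp[c] != G.cur) continue;
        for (int id = G.head[c]; id >= 0; id = G.nxt[id]) {
          if (W.species[id] != sp) continue;
          int st = W.state[id];
          if (st != stA && st != stB) continue;
          if (used[id] || W.acs[id] > 0) continue;
          if (need_cyt &&
              W.x[id] * W.x[id] + W.y[id] * W.y[id] + W.z[id] * W.z[id] <
                  C.rn2)
            continue;
          double ddx = W.x[id] - px, ddy = W.y[id] - py, ddz = W.z[id] - pz;
          double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
          if (d2 < best || (d2 == best && (best_id < 0 || id < best_id))) {
            best = d2;
            best_id = id;
          }
        }
      }
  return best_id;
}

static void do_step(World &W, const Ctx &C, Grid &G) {
  const double *kin = C.kin;
  const double *mech = C.mech;
  const double relw = kin[K_LIFE_RELW];
  const int ldist = (int)kin[K_LIFE_DIST];
  const double lcap = kin[K_LIFE_CAP];
  const int n = W.n();

  // ---- phase 1: coupling exchange + mechanical priming -------------------
  double m = modulus_multiplier(W.n_dep, mech[M_INCREMENT], mech[M_BETA],
                                (int)mech[M_CONV]);
  double g = mech[M_SIGMA_ON] > 0
                 ? force_factor(mech[M_ETA0], mech[M_K0], m)
                 : 0.0;
  double fref_coef = mech[M_FSCALE] * stress_coef(mech[M_ETA0], mech[M_K0]);
  double p_prime = kin[K_PRIME_MEAN] <= 0 ? 1.0 : 1.0 / kin[K_PRIME_MEAN];
  for (int i = 0; i < W.n_integrin; i++) {
    double F = fref_coef * g * W.Xpat[i];
    bool elig = F > 0 && F >= W.mt[i];
    if (W.state[i] == ST_BASAL) {
      if (elig && W.rng[1].unif() < p_prime) { W.state[i] = ST_ACTIVE; W.aux[i] = 0; }
    } else if (W.state[i] == ST_ACTIVE) {
      if (elig) W.aux[i] = 0;
      else {
        if (W.aux[i] <= 0) W.aux[i] = kin[K_OFF_DELAY];
        W.aux[i] -= 1.0;
        if (W.aux[i] <= 0) { W.state[i] = ST_BASAL; W.aux[i] = 0; W.acs[i] = 0; }
      }
    }
  }

  // ---- phase 2: Brownian movement ----------------------------------------
  // per-species step size and radial bounds, hoisted out of the hot loop
  double sig[11], blo[11], bhi[11];
  for (int sp = 0; sp < 11; sp++) {
    double D = 0;
    blo[sp] = C.rnuc; bhi[sp] = C.rcell;
    switch (sp) {
      case SP_FAK: case SP_RAS: case SP_RAF: case SP_MEK:
        D = kin[K_D_KINASE]; break;
      case SP_ERK: D = kin[K_D_KINASE]; blo[sp] = 0; break;  // shuttles
      case SP_RUNX2: case SP_COMPLEX:
        D = kin[K_D_NUCLEAR]; blo[sp] = 0; bhi[sp] = C.rnuc; break;
      case SP_RIBOSOME: D = kin[K_D_RIBOSOME]; break;
      case SP_PROTEIN: D = kin[K_D_PROTEIN]; break;
      case SP_MRNA: D = kin[K_D_MRNA]; break;  // lo resolved per agent
      default: break;
    }
    sig[sp] = D > 0 ? std::sqrt(2.0 * D) : 0.0;
  }
  Xoshiro &mrng = W.rng[0];
  for (int id = W.n_integrin; id < n; id++) {
    const int sp = W.species[id];
    const int st = W.state[id];
    if (st == ST_DEAD || st == ST_INERT || sp < 0) continue;
    const double s = sig[sp];
    if (s <= 0) continue;
    double lo = blo[sp];
    if (sp == SP_MRNA) {
      double r2 = W.x[id] * W.x[id] + W.y[id] * W.y[id] + W.z[id] * W.z[id];
      lo = (r2 > C.rn2) ? C.rnuc : 0;  // export only, no re-entry
    }
    W.x[id] += s * zig_norm(mrng);
    W.y[id] += s * zig_norm(mrng);
    W.z[id] += s * zig_norm(mrng);
    reflect(W.x[id], W.y[id], W.z[id], lo, bhi[sp]);
  }

  // ---- phase 3: reactions -------------------------------------------------
  std::vector<char> used(n, 0);

  // basal channel: rare spontaneous short-lived ERK phosphorylation
  if (kin[K_BASAL_RATE] > 0) {
    int nev = zig_pois(W.rng[3], kin[K_BASAL_RATE]);
    if (nev > 0) {
      std::vector<int> basal_erk;
      for (int id = 0; id < n; id++)
        if (W.species[id] == SP_ERK && W.state[id] == ST_BASAL &&
            W.acs[id] <= 0)
          basal_erk.push_back(id);
      for (int e = 0; e < nev && !basal_erk.empty(); e++) {
        int j = (int)(W.rng[3].unif() * basal_erk.size());
        if (j >= (int)basal_erk.size()) j = (int)basal_erk.size() - 1;
        int id = basal_erk[j];
        W.state[id] = ST_ACTIVE;
        W.life[id] = kin[K_BASAL_LO] +
                     W.rng[3].unif() * (kin[K_BASAL_HI] - kin[K_BASAL_LO]);
        basal_erk.erase(basal_erk.begin() + j);
      }
    }
  }

  // collect per-rule catalyst lists and build the substrate grid
  std::vector<int> cat[8];
  G.tick();
  for (int id = 0; id < n; id++) {
    int sp = W.species[id], st = W.state[id];
    if (st == ST_DEAD || st == ST_INERT) continue;
    switch (sp) {
      case SP_INTEGRIN:
        if (st == ST_ACTIVE) cat[0].push_back(id);
        break;
      case SP_FAK:
        if (st == ST_ACTIVE) cat[1].push_back(id);
        else if (st == ST_BASAL) G.insert(id, W.x[id], W.y[id], W.z[id]);
        break;
      case SP_RAS:
        if (st == ST_ACTIVE) cat[2].push_back(id);
        else if (st == ST_BASAL || st == ST_INTERMEDIATE)
          G.insert(id, W.x[id], W.y[id], W.z[id]);
        break;
      case SP_RAF:
        if (st == ST_ACTIVE) cat[3].push_back(id);
        else if (st == ST_BASAL) G.insert(id, W.x[id], W.y[id], W.z[id]);
        break;
      case SP_MEK:
        if (st == ST_ACTIVE) cat[4].push_back(id);
        else if (st == ST_BASAL) G.insert(id, W.x[id], W.y[id], W.z[id]);
        break;
      case SP_ERK:
        if (st == ST_ACTIVE) {
          double r2 = W.x[id] * W.x[id] + W.y[id] * W.y[id] + W.z[id] * W.z[id];
          if (r2 < C.rn2) cat[5].push_back(id);  // nuclear pERK
        } else if (st == ST_BASAL || st == ST_INTERMEDIATE)
          G.insert(id, W.x[id], W.y[id], W.z[id]);
        break;
      case SP_RUNX2:
        if (st == ST_ACTIVE) cat[6].push_back(id);
        else if (st == ST_BASAL) G.insert(id, W.x[id], W.y[id], W.z[id]);
        break;
      case SP_COMPLEX:
        if (st == ST_BASAL) G.insert(id, W.x[id], W.y[id], W.z[id]);
        break;
      case SP_RIBOSOME:
        if (st == ST_BASAL) G.insert(id, W.x[id], W.y[id], W.z[id]);
        break;
      case SP_MRNA: {
        if (st != ST_BASAL) break;
        double r2 = W.x[id] * W.x[id] + W.y[id] * W.y[id] + W.z[id] * W.z[id];
        if (r2 > C.rn2) cat[7].push_back(id);  // cytoplasmic, translatable
        break;
      }
      default: break;
    }
  }

  // rule table: substrate species, radius, prob, catalyst acs, product life
  struct Rule { int sub_sp; int kr, kp, kacs, klife; };
  static const Rule rules[7] = {
      {SP_FAK, K_R_IF, K_P_IF, K_ACS_INTEGRIN, K_LIFE_FAK},
      {SP_RAS, K_R_FR, K_P_FR, K_ACS_FAK, K_LIFE_RAS},
      {SP_RAF, K_R_RR, K_P_RR, K_ACS_RAS, K_LIFE_RAF},
      {SP_MEK, K_R_RM, K_P_RM, K_ACS_RAF, K_LIFE_MEK},
      {SP_ERK, K_R_ME, K_P_ME, K_ACS_MEK, K_LIFE_ERK},
      {SP_RUNX2, K_R_EX, K_P_EX, K_ACS_ERK, K_LIFE_RUNX2},
      {SP_COMPLEX, K_R_XC, K_P_XC, K_ACS_RUNX2, -1}};

  for (int r = 0; r < 7; r++) {
    const Rule &R = rules[r];
    std::vector<int> &cats = cat[r];
    int nc = (int)cats.size();
    for (int q = 0; q < nc; q++) {
      int cid = C.reverse ? cats[nc - 1 - q] : cats[q];
      if (used[cid] || W.acs[cid] > 0 || W.state[cid] != ST_ACTIVE) continue;
      bool distributive = (R.sub_sp == SP_ERK || R.sub_sp == SP_RAS);
      int stB = distributive ? ST_INTERMEDIATE : ST_BASAL;
      int sid = find_substrate(W, G, C, used, W.x[cid], W.y[cid], W.z[cid],
                               kin[R.kr], R.sub_sp, ST_BASAL, stB, false);
      if (sid < 0) continue;
      if (kin[R.kp] < 1.0 && W.rng[1].unif() >= kin[R.kp]) {
        used[cid] = 1;  // failed attempt consumes the catalyst's turn
        continue;
      }
      used[cid] = 1; used[sid] = 1;
      W.acs[cid] = kin[R.kacs];
      if (distributive && W.state[sid] == ST_BASAL) {
        // first of the two required activating encounters
        W.state[sid] = ST_INTERMEDIATE;
        int kli = (R.sub_sp == SP_ERK) ? K_LIFE_INTER : K_LIFE_RASINT;
        W.life[sid] = life_draw(W.rng[1], kin[kli], relw, ldist, lcap);
      } else if (R.sub_sp == SP_COMPLEX) {
        W.state[sid] = ST_TRANSCRIBING;
        W.aux[sid] = kin[K_TX_LO] +
                     W.rng[1].unif() * (kin[K_TX_HI] - kin[K_TX_LO]);
      } else {
        W.state[sid] = ST_ACTIVE;
        W.life[sid] = life_draw(W.rng[1], kin[R.klife], relw, ldist, lcap);
      }
    }
  }

  // translation: cytoplasmic mRNA + receptive ribosome
  {
    std::vector<int> &cats = cat[7];
    int nc = (int)cats.size();
    for (int q = 0; q < nc; q++) {
      int cid = C.reverse ? cats[nc - 1 - q] : cats[q];
      if (used[cid] || W.acs[cid] > 0) continue;
      int sid = find_substrate(W, G, C, used, W.x[cid], W.y[cid], W.z[cid],
                               kin[K_R_TR], SP_RIBOSOME, ST_BASAL, ST_BASAL,
                               false);
      if (sid < 0) continue;
      if (kin[K_P_TR] < 1.0 && W.rng[1].unif() >= kin[K_P_TR]) {
        used[cid] = 1;
        continue;
      }
      used[cid] = 1; used[sid] = 1;
      int yield = (int)std::lround(
          std::max(0.0, kin[K_YIELD_MEAN] +
                            kin[K_YIELD_SD] * zig_norm(W.rng[2])));
      int gene = W.gene[cid];
      for (int p = 0; p < yield; p++) {
        W.spawn(SP_PROTEIN, ST_BASAL, W.x[sid], W.y[sid], W.z[sid], gene, 0,
                0, kin[K_SECRETION_DELAY]);
        W.cum_tl[gene] += 1;
      }
      W.acs[cid] = kin[K_ACS_MRNA];
      W.acs[sid] = kin[K_ACS_RIBOSOME];
    }
  }

  // ---- phase 4: expression timers, decay, deposition ---------------------
  const int n2 = W.n();  // may have grown
  double wsum = kin[K_GENE_W0] + kin[K_GENE_W1] + kin[K_GENE_W2] +
                kin[K_GENE_W3];
  for (int id = 0; id < n2; id++) {
    int sp = W.species[id];
    if (sp == SP_COMPLEX && W.state[id] == ST_TRANSCRIBING) {
      W.aux[id] -= 1.0;
      if (W.aux[id] <= 0) {
        double u = W.rng[2].unif() * wsum;
        int gene = 0;
        double acc = kin[K_GENE_W0];
        while (gene < 3 && u >= acc) { gene++; acc += kin[K_GENE_W0 + gene]; }
        W.spawn(SP_MRNA, ST_BASAL, W.x[id], W.y[id], W.z[id], gene, 0, 0, 0);
        W.cum_tx[gene] += 1;
        W.state[id] = ST_BASAL;
        W.acs[id] = kin[K_ACS_COMPLEX];
        W.aux[id] = 0;
      }
    } else if (sp == SP_MRNA && W.state[id] != ST_INERT &&
               W.state[id] != ST_DEAD) {
      if (kin[K_MRNA_LIFETIME] > 0 &&
          W.rng[2].unif() < 1.0 / kin[K_MRNA_LIFETIME])
        W.kill(id);
    } else if (sp == SP_PROTEIN && W.state[id] != ST_DEAD) {
      W.aux[id] -= 1.0;
      if (W.aux[id] <= 0) {  // secreted and deposited in the ECM
        int gene = W.gene[id] >= 0 ? W.gene[id] : 0;
        W.kill(id);
        W.n_dep += 1;
        W.dep_gene[gene] += 1;
      }
    }
  }

  // ---- phase 5: ACS / lifetime tick --------------------------------------
  for (int id = 0; id < n2; id++) {
    int st = W.state[id];
    if (st == ST_DEAD || st == ST_INERT) continue;
    if (W.acs[id] > 0) W.acs[id] -= 1.0;
    int sp = W.species[id];
    if (sp == SP_INTEGRIN || sp == SP_MRNA || sp == SP_PROTEIN ||
        sp == SP_RIBOSOME || sp == SP_COMPLEX)
      continue;
    if (st == ST_ACTIVE) {
      W.life[id] -= 1.0;
      if (W.life[id] <= 0) {
        W.state[id] = ST_REFRACTORY;
        double post = 0;
        switch (sp) {
          case SP_FAK: post = kin[K_POST_FAK]; break;
          case SP_RAS: post = kin[K_POST_RAS]; break;
          case SP_RAF: post = kin[K_POST_RAF]; break;
          case SP_MEK: post = kin[K_POST_MEK]; break;
          case SP_ERK: post = kin[K_POST_ERK]; break;
          case SP_RUNX2: post = kin[K_POST_RUNX2]; break;
          default: break;
        }
        W.acs[id] = post;
        if (post <= 0) W.state[id] = ST_BASAL;
      }
    } else if (st == ST_INTERMEDIATE) {
      W.life[id] -= 1.0;
      if (W.life[id] <= 0) { W.state[id] = ST_BASAL; W.life[id] = 0; }
    } else if (st == ST_REFRACTORY) {
      if (W.acs[id] <= 0) W.state[id] = ST_BASAL;
    }
  }

  W.time_step += 1.0;
}

// sample row layout (keep in sync with .sample_cols in R)
static void record_sample(const World &W, const Ctx &C, const double *mech,
                          NumericMatrix &out, int row) {
  int active_int = 0, pfak = 0, aras = 0, praf = 0, pmek = 0, perk_c = 0,
      perk_n = 0, arunx2 = 0, txing = 0, mrna_live = 0;
  const int n = W.n();
  for (int id = 0; id < n; id++) {
    int sp = W.species[id], st = W.state[id];
    if (st == ST_DEAD) continue;
    switch (sp) {
      case SP_INTEGRIN: if (st == ST_ACTIVE) active_int++; break;
      case SP_FAK: if (st == ST_ACTIVE) pfak++; break;
      case SP_RAS: if (st == ST_ACTIVE) aras++; break;
      case SP_RAF: if (st == ST_ACTIVE) praf++; break;
      case SP_MEK: if (st == ST_ACTIVE) pmek++; break;
      case SP_ERK:
        if (st == ST_ACTIVE) {
          double r2 = W.x[id] * W.x[id] + W.y[id] * W.y[id] +
                      W.z[id] * W.z[id];
          if (r2 < C.rn2) perk_n++; else perk_c++;
        }
        break;
      case SP_RUNX2: if (st == ST_ACTIVE) arunx2++; break;
      case SP_COMPLEX: if (st == ST_TRANSCRIBING) txing++; break;
      case SP_MRNA: mrna_live++; break;
      default: break;
    }
  }
  double m = modulus_multiplier(W.n_dep, mech[M_INCREMENT], mech[M_BETA],
                                (int)mech[M_CONV]);
  int j = 0;
  out(row, j++) = W.time_step;
  out(row, j++) = active_int;
  out(row, j++) = pfak;
  out(row, j++) = aras;
  out(row, j++) = praf;
  out(row, j++) = pmek;
  out(row, j++) = perk_c;
  out(row, j++) = perk_n;
  out(row, j++) = arunx2;
  out(row, j++) = txing;
  out(row, j++) = mrna_live;
  out(row, j++) = W.dep_gene[0];
  out(row, j++) = W.dep_gene[1];
  out(row, j++) = W.dep_gene[2];
  out(row, j++) = W.dep_gene[3];
  out(row, j++) = W.n_dep;
  out(row, j++) = mech[M_MU_BASE] * m;
  out(row, j++) = W.cum_tx[0] + W.cum_tx[1] + W.cum_tx[2] + W.cum_tx[3];
  out(row, j++) = W.cum_tl[0] + W.cum_tl[1] + W.cum_tl[2] + W.cum_tl[3];
}

// [[Rcpp::export]]
List abm_run_cpp(List world, NumericVector mech, NumericVector kin,
                 int n_steps, int sample_every, bool reverse_order = false) {
  if (!zig_ready) zig_setup();
  if (kin.size() != K_N_PARAMS) stop("kinetics vector length mismatch");
  if (mech.size() != M_N_PARAMS) stop("mechanics vector length mismatch");
  World W = world_from_list(world);
  Ctx C;
  C.kin = &kin[0];
  C.mech = &mech[0];
  C.rcell = mech[M_RCELL];
  C.rnuc = mech[M_RNUC];
  C.rc2 = C.rcell * C.rcell;
  C.rn2 = C.rnuc * C.rnuc;
  C.reverse = reverse_order;

  Grid G;
  G.init(C.rcell, 400.0, W.n() + 1024);

  int nsamp = 0;
  if (sample_every > 0)
    for (int s = 0; s <= n_steps; s++)
      if (((long long)W.time_step + s) % sample_every == 0) nsamp++;
  NumericMatrix samples(std::max(nsamp, 0), 19);
  int row = 0;
  for (int s = 0; s <= n_steps; s++) {
    if (sample_every > 0 && ((long long)W.time_step) % sample_every == 0)
      record_sample(W, C, &mech[0], samples, row++);
    if (s == n_steps) break;
    do_step(W, C, G);
    if ((s & 1023) == 1023) Rcpp::checkUserInterrupt();
  }
  return List::create(_["world"] = world_to_list(W),
                      _["samples"] = samples);
}

// brute-force-equivalent spatial query used by tests and by the R-level
// neighbour API: all agent indices (1-based) within `radius` of agent `id`
// [[Rcpp::export]]
IntegerVector neighbours_within_cpp(List world, int id1, double radius) {
  World W = world_from_list(world);
  int id = id1 - 1;
  if (id < 0 || id >= W.n()) stop("agent id out of range");
  std::vector<int> res;
  double r2 = radius * radius;
  for (int j = 0; j < W.n(); j++) {
    if (j == id || W.state[j] == ST_DEAD) continue;
    double dx = W.x[j] - W.x[id], dy = W.y[j] - W.y[id],
           dz = W.z[j] - W.z[id];
    if (dx * dx + dy * dy + dz * dz <= r2) res.push_back(j + 1);
  }
  return IntegerVector(res.begin(), res.end());
}

// grid-indexed variant of the same query (the engine's spatial index),
// kept independent of the linear scan so the two can cross-check
// [[Rcpp::export]]
IntegerVector grid_neighbours_cpp(List world, int id1, double radius,
                                  double rcell) {
  World W = world_from_list(world);
  int id = id1 - 1;
  if (id < 0 || id >= W.n()) stop("agent id out of range");
  Grid G;
  G.init(rcell, 400.0, W.n() + 16);
  G.tick();
  for (int j = 0; j < W.n(); j++)
    if (W.state[j] != ST_DEAD && j != id)
      G.insert(j, W.x[j], W.y[j], W.z[j]);
  std::vector<int> res;
  double r2 = radius * radius;
  int span = (int)std::ceil(radius / G.cell);
  int ix = (int)((W.x[id] - G.origin) / G.cell),
      iy = (int)((W.y[id] - G.origin) / G.cell),
      iz = (int)((W.z[id] - G.origin) / G.cell);
  for (int dx = -span; dx <= span; dx++)
    for (int dy = -span; dy <= span; dy++)
      for (int dz = -span; dz <= span; dz++) {
        int cx = ix + dx, cy = iy + dy, cz = iz + dz;
        if (cx < 0 || cy < 0 || cz < 0 || cx >= G.dim || cy >= G.dim ||
            cz >= G.dim)
          continue;
        int c = (cx * G.dim + cy) * G.dim + cz;
        if (G.stamp[c] != G.cur) continue;
        for (int j = G.head[c]; j >= 0; j = G.nxt[j]) {
          double ddx = W.x[j] - W.x[id], ddy = W.y[j] - W.y[id],
                 ddz = W.z[j] - W.z[id];
          if (ddx * ddx + ddy * ddy + ddz * ddz <= r2) res.push_back(j + 1);
        }
      }
  std::sort(res.begin(), res.end());
  return IntegerVector(res.begin(), res.end());
}

// standalone Brownian kernel (shared ziggurat + reflection), for the
// agents-module API and its statistical tests
// [[Rcpp::export]]
List brownian_step_cpp(NumericMatrix pos, double D, double dt, double lo,
                       double hi, IntegerVector rng_state) {
  if (!zig_ready) zig_setup();
  Xoshiro st[4];
  rng_unpack(rng_state, st);
  NumericMatrix out(pos.nrow(), 3);
  double s = std::sqrt(2.0 * D * dt);
  for (int i = 0; i < pos.nrow(); i++) {
    double px = pos(i, 0) + s * zig_norm(st[0]);
    double py = pos(i, 1) + s * zig_norm(st[0]);
    double pz = pos(i, 2) + s * zig_norm(st[0]);
    reflect(px, py, pz, lo, hi);
    out(i, 0) = px; out(i, 1) = py; out(i, 2) = pz;
  }
  IntegerVector rv(32);
  rng_pack(rv, st);
  return List::create(_["pos"] = out, _["rng"] = rv);
}
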