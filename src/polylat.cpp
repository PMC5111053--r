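// Dynamic Monte Carlo engine for a single fluctuating-bond polymer on the
// simple cubic lattice.  Bond lengths are restricted to {1, sqrt2, sqrt3}
// ({1, sqrt2} in-plane), monomers are self-avoiding, bonds may not cross,
// and moves are single-monomer unit-vector displacements accepted with the
// Metropolis probability min(1, exp(-dE)) at k_B T = 1.
//
// Boundary modes: 0 = bulk3d (periodic x,y,z), 1 = slab (periodic x,y,
// impenetrable attracting wall at z = 0, monomers on z >= 1, reflecting top
// at z = Lz - 1), 2 = plane2d (one z-plane, periodic x,y).

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded via splitmix64.  Self-contained so that replica
// streams are reproducible from recorded integer seeds independently of the
// R session RNG state.
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) s[i] = splitmix(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline int below(int m) { return (int)(unif() * m); }
};

// ---------------------------------------------------------------------------
// Exact integer segment geometry.
struct V3 { long long x, y, z; };

static inline V3 vsub(const V3 &a, const V3 &b) {
  return V3{a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline V3 vcross(const V3 &a, const V3 &b) {
  return V3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
            a.x * b.y - a.y * b.x};
}
static inline long long vdot(const V3 &a, const V3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline bool vzero(const V3 &a) { return !(a.x || a.y || a.z); }

// Closed segments [a,b] and [c,d] share at least one point?  All-integer:
// coplanarity via the scalar triple product, then the rational parameters
// s = ((c-a) x v).n / |n|^2, t = ((c-a) x u).n / |n|^2 with n = u x v must
// both lie in [0, 1]; parallel segments are handled by collinear-overlap.
static bool seg_intersect(const V3 &a, const V3 &b, const V3 &c, const V3 &d) {
  // bounding-box rejection (also makes the exact branch rare)
  if (std::max(a.x, b.x) < std::min(c.x, d.x) ||
      std::min(a.x, b.x) > std::max(c.x, d.x) ||
      std::max(a.y, b.y) < std::min(c.y, d.y) ||
      std::min(a.y, b.y) > std::max(c.y, d.y) ||
      std::max(a.z, b.z) < std::min(c.z, d.z) ||
      std::min(a.z, b.z) > std::max(c.z, d.z)) return false;
  V3 u = vsub(b, a), v = vsub(d, c), w = vsub(c, a);
  V3 nvec = vcross(u, v);
  if (!vzero(nvec)) {
    if (vdot(nvec, w) != 0) return false;   // skew: not coplanar
    long long den = vdot(nvec, nvec);
    long long s_num = vdot(vcross(w, v), nvec);
    long long t_num = vdot(vcross(w, u), nvec);
    return s_num >= 0 && s_num <= den && t_num >= 0 && t_num <= den;
  }
  // parallel
  if (!vzero(vcross(w, u))) return false;   // parallel, not collinear
  long long uu = vdot(u, u);
  long long t0 = vdot(w, u);
  long long t1 = vdot(vsub(d, a), u);
  long long lo = std::min(t0, t1), hi = std::max(t0, t1);
  return !(hi < 0 || lo > uu);
}

static inline long long img_shift(long long d, int l) {
  // multiple of l nearest to d (minimum-image translation)
  return (long long)llround((double)d / l) * l;
}

static inline long long min_image(long long d, int l) {
  // branchy minimum image: cheap because |d| <= l in almost every call
  long long h = l / 2;
  while (d > h) d -= l;
  while (d < -h) d += l;
  return d;
}

static const int DX[6] = {1, -1, 0, 0, 0, 0};
static const int DY[6] = {0, 0, 1, -1, 0, 0};
static const int DZ[6] = {0, 0, 0, 0, 1, -1};

// ---------------------------------------------------------------------------
struct Sim {
  int n, mode, lx, ly, lz;
  double epp, eps;
  // unwrapped positions (true displacements); wrapped copies for the grid
  std::vector<int> px, py, pz, wx, wy, wz;
  std::vector<uint8_t> occ;   // site -> monomer index + 1, 0 if empty (n <= 254)
  long long npp, nps;
  long long sumx, sumy, sumz; // running sums of unwrapped coords (for COM)
  int zmin_cur;               // lower z bound for moves (slab phases)
  long long attempted, accepted;
  Xoshiro rng;
  int ndirs, nc_dirs, max_bond_sq;

  Sim(int n_, int mode_, double epp_, double eps_, int lx_, int ly_, int lz_,
      uint64_t seed)
    : n(n_), mode(mode_), lx(lx_), ly(ly_), lz(lz_), epp(epp_), eps(eps_),
      px(n_), py(n_), pz(n_), wx(n_), wy(n_), wz(n_),
      occ((size_t)lx_ * ly_ * lz_, 0),
      npp(0), nps(0), sumx(0), sumy(0), sumz(0), zmin_cur(mode_ == 1 ? 1 : 0),
      attempted(0), accepted(0), rng(seed) {
    ndirs = (mode == 2) ? 4 : 6;
    nc_dirs = ndirs;                 // contact directions = move directions
    max_bond_sq = (mode == 2) ? 2 : 3;
  }

  inline int wrap(int a, int l) const { int r = a % l; return r < 0 ? r + l : r; }
  inline size_t sidx(int x, int y, int z) const {
    return ((size_t)z * ly + y) * lx + x;
  }
  // occupant (monomer index, or -1) at wrapped site; z already wrapped in
  // bulk, raw in slab/plane (out-of-range z means an empty/non-site)
  inline int occ_at(int x, int y, int z) const {
    if (mode != 0 && (z < 0 || z >= lz)) return -1;
    uint8_t v = occ[sidx(x, y, z)];
    return v == 0 ? -1 : v - 1;
  }

  void place_positions(const std::vector<int> &x, const std::vector<int> &y,
                       const std::vector<int> &z) {
    std::fill(occ.begin(), occ.end(), 0);
    sumx = sumy = sumz = 0;
    for (int i = 0; i < n; i++) {
      px[i] = x[i]; py[i] = y[i]; pz[i] = z[i];
      wx[i] = wrap(x[i], lx); wy[i] = wrap(y[i], ly);
      wz[i] = (mode == 0) ? wrap(z[i], lz) : z[i];
      if (mode != 0 && (wz[i] < 0 || wz[i] >= lz))
        stop("initial position outside the box in z");
      size_t s = sidx(wx[i], wy[i], wz[i]);
      if (occ[s] != 0) stop("initial positions violate self-avoidance");
      occ[s] = i + 1;
      sumx += px[i]; sumy += py[i]; sumz += pz[i];
    }
    recount_contacts(npp, nps);
  }

  // compact boustrophedon snake in one z-plane: small extent, unit bonds
  void init_snake(int z0) {
    int m = (int)std::ceil(std::sqrt((double)n));
    if (m > lx || (n + m - 1) / m > ly)
      stop("box too small for the initial configuration");
    std::vector<int> x(n), y(n), z(n, z0);
    int x0 = lx / 2 - m / 2, y0 = ly / 2 - m / 2;
    for (int i = 0; i < n; i++) {
      int r = i / m, c = i % m;
      x[i] = x0 + ((r % 2 == 0) ? c : m - 1 - c);
      y[i] = y0 + r;
    }
    place_positions(x, y, z);
  }

  // from-scratch minimum-image recount of non-bonded NN pairs and surface
  // contacts (used for validation and delta-energy cross-checks)
  void recount_contacts(long long &cpp, long long &cps) const {
    cpp = 0; cps = 0;
    for (int i = 0; i < n; i++) {
      for (int j = i + 2; j < n; j++) {
        long long dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
        dx -= img_shift(dx, lx);
        dy -= img_shift(dy, ly);
        if (mode == 0) dz -= img_shift(dz, lz);
        if (dx * dx + dy * dy + dz * dz == 1) cpp++;
      }
      if (mode == 1 && pz[i] == 1) cps++;
    }
  }

  // number of non-bonded unit-distance neighbours monomer i would have at
  // wrapped site (x, y, z); monomer i itself and its bonded neighbours are
  // excluded via the index rule |i - j| >= 2
  inline int local_contacts(int i, int x, int y, int z) const {
    int cnt = 0;
    for (int d = 0; d < nc_dirs; d++) {
      int nx = x + DX[d]; if (nx == lx) nx = 0; else if (nx < 0) nx = lx - 1;
      int ny = y + DY[d]; if (ny == ly) ny = 0; else if (ny < 0) ny = ly - 1;
      int nz = z + DZ[d];
      if (mode == 0) { if (nz == lz) nz = 0; else if (nz < 0) nz = lz - 1; }
      int j = occ_at(nx, ny, nz);
      if (j >= 0 && (j >= i + 2 || j <= i - 2)) cnt++;
    }
    return cnt;
  }

  // would moving monomer i to B make either displaced bond cross any other
  // bond?  One pass over all bonds; consecutive bonds sharing a monomer are
  // exempt.  Bonds are at most sqrt(3) long, so a bond whose first monomer
  // sits 4 or more sites away from B along any axis (minimum image) cannot
  // touch either displaced bond.
  bool move_crosses(int i, const V3 &B) const {
    const bool has1 = i > 0, has2 = i < n - 1;
    V3 A1{0, 0, 0}, A2{0, 0, 0};
    if (has1) A1 = V3{px[i - 1], py[i - 1], pz[i - 1]};
    if (has2) A2 = V3{px[i + 1], py[i + 1], pz[i + 1]};
    for (int k = 0; k + 1 < n; k++) {
      bool t1 = has1 && (k < i - 2 || k > i);
      bool t2 = has2 && (k < i - 1 || k > i + 1);
      if (!t1 && !t2) continue;
      long long dx = min_image(px[k] - B.x, lx);
      if (dx >= 4 || dx <= -4) continue;
      long long dy = min_image(py[k] - B.y, ly);
      if (dy >= 4 || dy <= -4) continue;
      long long dz = pz[k] - B.z;
      if (mode == 0) dz = min_image(dz, lz);
      if (dz >= 4 || dz <= -4) continue;
      V3 c{B.x + dx, B.y + dy, B.z + dz};
      V3 d{c.x + (px[k + 1] - px[k]), c.y + (py[k + 1] - py[k]),
           c.z + (pz[k + 1] - pz[k])};
      if (t1 && seg_intersect(A1, B, c, d)) return true;
      if (t2 && seg_intersect(A2, B, c, d)) return true;
    }
    return false;
  }

  // one attempted single-monomer move; returns true if accepted
  bool attempt() {
    attempted++;
    int i = rng.below(n);
    int d = rng.below(ndirs);
    int ux = px[i] + DX[d], uy = py[i] + DY[d], uz = pz[i] + DZ[d];
    if (mode == 1 && (uz < zmin_cur || uz > lz - 1)) return false;
    int nx = wx[i] + DX[d]; if (nx == lx) nx = 0; else if (nx < 0) nx = lx - 1;
    int ny = wy[i] + DY[d]; if (ny == ly) ny = 0; else if (ny < 0) ny = ly - 1;
    int nz = wz[i] + DZ[d];
    if (mode == 0) { if (nz == lz) nz = 0; else if (nz < 0) nz = lz - 1; }
    if (occ[sidx(nx, ny, nz)] != 0) return false;
    // bond lengths (unwrapped differences are the physical bond vectors)
    if (i > 0) {
      long long bx = ux - px[i - 1], by = uy - py[i - 1], bz = uz - pz[i - 1];
      long long s = bx * bx + by * by + bz * bz;
      if (s > max_bond_sq) return false;
    }
    if (i < n - 1) {
      long long bx = ux - px[i + 1], by = uy - py[i + 1], bz = uz - pz[i + 1];
      long long s = bx * bx + by * by + bz * bz;
      if (s > max_bond_sq) return false;
    }
    // non-crossing of the two displaced bonds against all non-adjacent bonds
    if (n > 2) {
      V3 B{ux, uy, uz};
      if (move_crosses(i, B)) return false;
    }
    // energy change from local neighbourhoods only (n_PP is tracked even
    // when E_PP = 0: the trajectory records contact counts)
    double dE = 0.0;
    int dnpp = 0;
    if (n > 2) {
      dnpp = local_contacts(i, nx, ny, nz) - local_contacts(i, wx[i], wy[i], wz[i]);
      if (epp != 0.0) dE -= dnpp * epp;
    }
    int dnps = 0;
    if (mode == 1) {
      dnps = (uz == 1) - (pz[i] == 1);
      dE -= dnps * eps;
    }
    if (dE > 0.0 && rng.unif() >= std::exp(-dE)) return false;
    // accept
    occ[sidx(wx[i], wy[i], wz[i])] = 0;
    occ[sidx(nx, ny, nz)] = i + 1;
    sumx += ux - px[i]; sumy += uy - py[i]; sumz += uz - pz[i];
    px[i] = ux; py[i] = uy; pz[i] = uz;
    wx[i] = nx; wy[i] = ny; wz[i] = nz;
    npp += dnpp; nps += dnps;
    accepted++;
    return true;
  }

  void run_mcs_block(long long mcs, int check_every) {
    for (long long t = 0; t < mcs; t++) {
      for (int k = 0; k < n; k++) attempt();
      if (check_every > 0 && (t + 1) % check_every == 0) validate();
      if ((t & 0x3FFF) == 0x3FFF) Rcpp::checkUserInterrupt();
    }
  }

  void validate() const {
    // self-avoidance + wrapped/unwrapped consistency
    std::vector<uint8_t> occ2((size_t)lx * ly * lz, 0);
    for (int i = 0; i < n; i++) {
      int x = wrap(px[i], lx), y = wrap(py[i], ly);
      int z = (mode == 0) ? wrap(pz[i], lz) : pz[i];
      if (x != wx[i] || y != wy[i] || z != wz[i])
        stop("invariant violation: wrapped/unwrapped positions inconsistent");
      if (mode != 0 && (z < (mode == 1 ? 1 : 0) || z >= lz))
        stop("invariant violation: monomer outside allowed z range");
      size_t s = sidx(x, y, z);
      if (occ2[s] != 0) stop("invariant violation: self-avoidance broken");
      occ2[s] = i + 1;
      if (occ[s] != i + 1) stop("invariant violation: occupancy grid stale");
    }
    // bond lengths
    for (int i = 0; i + 1 < n; i++) {
      long long bx = px[i + 1] - px[i], by = py[i + 1] - py[i],
                bz = pz[i + 1] - pz[i];
      long long s = bx * bx + by * by + bz * bz;
      if (s < 1 || s > max_bond_sq)
        stop("invariant violation: bond length outside allowed set");
    }
    // non-crossing, all non-adjacent bond pairs
    for (int a = 0; a + 1 < n; a++) {
      V3 A1{px[a], py[a], pz[a]}, A2{px[a + 1], py[a + 1], pz[a + 1]};
      for (int b = a + 2; b + 1 < n; b++) {
        V3 C{px[b], py[b], pz[b]}, D{px[b + 1], py[b + 1], pz[b + 1]};
        long long sx = img_shift(C.x - A1.x, lx);
        long long sy = img_shift(C.y - A1.y, ly);
        long long sz = (mode == 0) ? img_shift(C.z - A1.z, lz) : 0;
        C.x -= sx; C.y -= sy; C.z -= sz;
        D.x -= sx; D.y -= sy; D.z -= sz;
        if (seg_intersect(A1, A2, C, D))
          stop("invariant violation: bonds intersect");
      }
    }
    long long cpp, cps;
    recount_contacts(cpp, cps);
    if (cpp != npp || cps != nps)
      stop("invariant violation: cached contact counts diverged from recount");
  }

  double rg_sq() const {
    double cx = (double)sumx / n, cy = (double)sumy / n, cz = (double)sumz / n;
    double acc = 0.0;
    for (int i = 0; i < n; i++) {
      double dx = px[i] - cx, dy = py[i] - cy, dz = pz[i] - cz;
      acc += dx * dx + dy * dy + dz * dz;
    }
    return acc / n;
  }
};

// ---------------------------------------------------------------------------
// [[Rcpp::export]]
bool segments_intersect_cpp(IntegerVector a1, IntegerVector a2,
                            IntegerVector b1, IntegerVector b2) {
  V3 A{a1[0], a1[1], a1[2]}, B{a2[0], a2[1], a2[2]};
  V3 C{b1[0], b1[1], b1[2]}, D{b2[0], b2[1], b2[2]};
  return seg_intersect(A, B, C, D);
}

// [[Rcpp::export]]
IntegerVector count_contacts_cpp(IntegerMatrix pos, int mode,
                                 IntegerVector box) {
  int n = pos.nrow();
  int lx = box[0], ly = box[1], lz = box[2];
  long long cpp = 0, cps = 0;
  for (int i = 0; i < n; i++) {
    for (int j = i + 2; j < n; j++) {
      long long dx = pos(i, 0) - pos(j, 0);
      long long dy = pos(i, 1) - pos(j, 1);
      long long dz = pos(i, 2) - pos(j, 2);
      dx -= img_shift(dx, lx);
      dy -= img_shift(dy, ly);
      if (mode == 0) dz -= img_shift(dz, lz);
      if (dx * dx + dy * dy + dz * dz == 1) cpp++;
    }
    if (mode == 1 && pos(i, 2) == 1) cps++;
  }
  return IntegerVector::create((int)cpp, (int)cps);
}

// [[Rcpp::export]]
IntegerMatrix propose_moves_cpp(int n_prop, int n, int mode, double seed) {
  Xoshiro rng((uint64_t)seed);
  int ndirs = (mode == 2) ? 4 : 6;
  IntegerMatrix out(n_prop, 2);
  for (int k = 0; k < n_prop; k++) {
    out(k, 0) = rng.below(n) + 1;   // 1-based monomer index
    out(k, 1) = rng.below(ndirs) + 1;
  }
  return out;
}

// [[Rcpp::export]]
List run_chain_cpp(int n, int mode, double e_pp, double e_ps,
                   IntegerVector box,
                   double equil_mcs, double settle_mcs, double production_mcs,
                   int sample_interval, double adsorb_cap_mcs,
                   bool adsorb_protocol, double seed, int check_every,
                   bool record_positions,
                   Nullable<IntegerMatrix> init_positions) {
  if (n < 1) stop("n must be >= 1");
  if (n > 254) stop("n must be <= 254 (occupancy grid stores byte indices)");
  int lx = box[0], ly = box[1], lz = box[2];
  if (mode == 2 && lz != 1) stop("plane2d requires L_z = 1");
  if (sample_interval < 1) stop("sample_interval must be >= 1");
  Sim sim(n, mode, e_pp, e_ps, lx, ly, lz, (uint64_t)seed);

  if (init_positions.isNotNull()) {
    IntegerMatrix ip(init_positions);
    if (ip.nrow() != n || ip.ncol() != 3)
      stop("init_positions must be an n x 3 integer matrix");
    std::vector<int> x(n), y(n), z(n);
    for (int i = 0; i < n; i++) { x[i] = ip(i, 0); y[i] = ip(i, 1); z[i] = ip(i, 2); }
    sim.place_positions(x, y, z);
    sim.validate();
  } else if (mode == 1 && adsorb_protocol) {
    int zv = (lz + 3) / 4;                 // virtual repulsive wall at Lz/4
    int ztop = lz - 1;
    sim.init_snake(std::min(ztop, (zv + ztop) / 2));
  } else {
    int z0 = (mode == 2) ? 0 : (mode == 1 ? std::max(1, lz / 2) : lz / 2);
    sim.init_snake(z0);
  }

  double adsorption_wait = NA_REAL;
  if (mode == 1 && adsorb_protocol && init_positions.isNull()) {
    // phase 1: equilibrate above the virtual wall
    sim.zmin_cur = (lz + 3) / 4;
    sim.run_mcs_block((long long)equil_mcs, check_every);
    // phase 2: release the wall, run until first surface contact
    sim.zmin_cur = 1;
    long long waited = 0, cap = (long long)adsorb_cap_mcs;
    while (sim.nps == 0) {
      if (waited >= cap)
        stop("chain failed to adsorb within adsorb_cap_mcs (%d MCS)", (int)cap);
      sim.run_mcs_block(1, 0);
      waited++;
      if ((waited & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
    }
    adsorption_wait = (double)waited;
    // phase 3: settle into the adsorbed equilibrium state
    sim.run_mcs_block((long long)settle_mcs, check_every);
  } else {
    sim.run_mcs_block((long long)equil_mcs, check_every);
  }

  // production
  long long prod = (long long)production_mcs;
  int nframes = (int)(prod / sample_interval) + 1;
  NumericVector times(nframes), rg(nframes), energy(nframes);
  NumericMatrix com(nframes, 3);
  IntegerMatrix ree(nframes, 3);
  IntegerVector fnpp(nframes), fnps(nframes);
  IntegerVector posrec;
  if (record_positions) posrec = IntegerVector((R_xlen_t)nframes * n * 3);

  long long att0 = sim.attempted, acc0 = sim.accepted;
  int desorbed = 0;
  int frame = 0;
  auto record = [&](long long t) {
    times[frame] = (double)t;
    com(frame, 0) = (double)sim.sumx / n;
    com(frame, 1) = (double)sim.sumy / n;
    com(frame, 2) = (double)sim.sumz / n;
    ree(frame, 0) = sim.px[n - 1] - sim.px[0];
    ree(frame, 1) = sim.py[n - 1] - sim.py[0];
    ree(frame, 2) = sim.pz[n - 1] - sim.pz[0];
    rg[frame] = sim.rg_sq();
    fnpp[frame] = (int)sim.npp;
    fnps[frame] = (int)sim.nps;
    energy[frame] = -(double)sim.npp * e_pp - (double)sim.nps * e_ps;
    if (mode == 1 && sim.nps == 0) desorbed++;
    if (record_positions) {
      R_xlen_t off = (R_xlen_t)frame * n * 3;
      for (int i = 0; i < n; i++) {
        posrec[off + 3 * i] = sim.px[i];
        posrec[off + 3 * i + 1] = sim.py[i];
        posrec[off + 3 * i + 2] = sim.pz[i];
      }
    }
    frame++;
  };

  record(0);
  for (long long t = 0; t < prod; t++) {
    for (int k = 0; k < n; k++) sim.attempt();
    if (check_every > 0 && (t + 1) % check_every == 0) sim.validate();
    if ((t + 1) % sample_interval == 0 && frame < nframes) record(t + 1);
    if ((t & 0x3FFF) == 0x3FFF) Rcpp::checkUserInterrupt();
  }
  sim.validate();

  long long cpp, cps;
  sim.recount_contacts(cpp, cps);
  IntegerMatrix fin(n, 3), finw(n, 3);
  for (int i = 0; i < n; i++) {
    fin(i, 0) = sim.px[i]; fin(i, 1) = sim.py[i]; fin(i, 2) = sim.pz[i];
    finw(i, 0) = sim.wx[i]; finw(i, 1) = sim.wy[i]; finw(i, 2) = sim.wz[i];
  }

  double att_prod = (double)(sim.attempted - att0);
  List out = List::create(
    _["times"] = times,
    _["com"] = com,
    _["end_to_end"] = ree,
    _["rg_sq"] = rg,
    _["n_pp"] = fnpp,
    _["n_ps"] = fnps,
    _["energy"] = energy,
    _["acceptance_rate"] = att_prod > 0 ? (double)(sim.accepted - acc0) / att_prod : NA_REAL,
    _["desorbed_fraction"] = (mode == 1) ? (double)desorbed / nframes : 0.0,
    _["adsorption_wait_mcs"] = adsorption_wait,
    _["final_positions"] = fin,
    _["final_wrapped"] = finw,
    _["n_pp_final"] = (int)sim.npp,
    _["n_ps_final"] = (int)sim.nps,
    _["n_pp_recount"] = (int)cpp,
    _["n_ps_recount"] = (int)cps,
    _["positions"] = record_positions ? (SEXP)posrec : R_NilValue);
  return out;
}
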