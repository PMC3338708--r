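// Cubic-lattice Go-model Monte Carlo engine.
//
// The chain lives on Z^3; occupancy is tracked on a 64^3 grid indexed by the
// low 6 bits of each coordinate.  Because a connected N-bead chain (N <= 60)
// spans less than 64 lattice units in any direction, the masked lookup is
// collision-free, so the chain may drift freely without re-centring.
//
// Energies are kept as integers: E = -(number of favorable contacts), with
// epsilon = 1.  Callers work in reduced units and rescale temperature by
// epsilon on the R side.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <functional>
#include <vector>

using namespace Rcpp;

static const int DX[6] = {1, -1, 0, 0, 0, 0};
static const int DY[6] = {0, 0, 1, -1, 0, 0};
static const int DZ[6] = {0, 0, 0, 0, 1, -1};

// xoshiro256++ seeded through splitmix64: identical streams on every platform.
struct RNG {
  uint64_t s[4];
  explicit RNG(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 1.1102230246251565e-16; }
  inline int below(int n) { return (int)(next() % (uint64_t)n); }
};

struct Move {
  int kind;  // 1 = single bead, 2 = crankshaft pair
  int b1, b2;
  int x1, y1, z1, x2, y2, z2;
};

struct Sim {
  int N;
  std::vector<int> px, py, pz;
  std::vector<int16_t> grid;   // 64^3 occupancy, bead index + 1
  const uint8_t* fav;          // N*N favorable-pair matrix; NULL = homopolymer
  int E;                       // -(favorable contacts)
  bool confined;
  int bx, by, bz;
  int tw = 1;  // extra weight of the terminus-terminus contact (collapse bias)
  double invT;
  double expTab[64];

  void set_temperature(double T) {
    invT = 1.0 / T;
    for (int k = 0; k < 64; ++k) expTab[k] = std::exp(-k * invT);
  }
  inline int occ(int x, int y, int z) const {
    return grid[((x & 63) << 12) | ((y & 63) << 6) | (z & 63)];
  }
  inline void setocc(int x, int y, int z, int v) {
    grid[((x & 63) << 12) | ((y & 63) << 6) | (z & 63)] = (int16_t)v;
  }
  inline bool in_box(int x, int y, int z) const {
    return !confined ||
           (x >= 0 && x < bx && y >= 0 && y < by && z >= 0 && z < bz);
  }
  inline bool favorable(int a, int b) const {
    int d = a - b;
    if (d < 0) d = -d;
    if (d < 2) return false;
    return fav ? fav[a * N + b] != 0 : true;
  }
  inline int contactW(int a, int b) const {
    if (!favorable(a, b)) return 0;
    if (tw != 1 && ((a == 0 && b == N - 1) || (b == 0 && a == N - 1)))
      return tw;
    return 1;
  }

  void init(const IntegerMatrix& coords, const uint8_t* favm, bool conf_,
            int bx_, int by_, int bz_) {
    N = coords.nrow();
    if (N > 60) stop("chain length must be <= 60 for the lattice engine");
    px.assign(N, 0);
    py.assign(N, 0);
    pz.assign(N, 0);
    grid.assign(1 << 18, 0);
    fav = favm;
    confined = conf_;
    bx = bx_;
    by = by_;
    bz = bz_;
    for (int i = 0; i < N; ++i) {
      px[i] = coords(i, 0);
      py[i] = coords(i, 1);
      pz[i] = coords(i, 2);
      if (occ(px[i], py[i], pz[i]))
        stop("starting conformation has overlapping beads");
      setocc(px[i], py[i], pz[i], i + 1);
    }
    E = 0;
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 6; ++d) {
        int o = occ(px[i] + DX[d], py[i] + DY[d], pz[i] + DZ[d]);
        if (o) {
          int b = o - 1;
          if (b > i) E -= contactW(i, b);
        }
      }
  }

  inline int localC(int m, int x, int y, int z) const {
    int c = 0;
    for (int d = 0; d < 6; ++d) {
      int o = occ(x + DX[d], y + DY[d], z + DZ[d]);
      if (o) c += contactW(m, o - 1);
    }
    return c;
  }

  // Candidate move for (bead, slot).  End beads have 6 slots (one per target
  // direction around the anchor); interior beads have 7: slot 0 = corner
  // flip, 1-3 = crankshaft with the right-hand pair (90/180/270 degrees),
  // 4-6 = crankshaft with the left-hand pair.  The slot space is fixed per
  // bead, and the reverse of every realizable move occupies exactly one slot
  // at the same bead, so the proposal distribution is symmetric; illegal
  // slots are null proposals that consume one MC step.
  bool candidate(int i, int slot, Move& mv) const {
    if (i == 0 || i == N - 1) {
      int a = (i == 0) ? 1 : N - 2;
      int tx = px[a] + DX[slot], ty = py[a] + DY[slot], tz = pz[a] + DZ[slot];
      if (!in_box(tx, ty, tz)) return false;
      if (tx == px[i] && ty == py[i] && tz == pz[i]) return false;
      if (occ(tx, ty, tz)) return false;
      mv = {1, i, -1, tx, ty, tz, 0, 0, 0};
      return true;
    }
    if (slot == 0) {  // corner flip
      int ax = px[i + 1] - px[i - 1], ay = py[i + 1] - py[i - 1],
          az = pz[i + 1] - pz[i - 1];
      if (ax * ax + ay * ay + az * az != 2) return false;
      int tx = px[i - 1] + px[i + 1] - px[i],
          ty = py[i - 1] + py[i + 1] - py[i],
          tz = pz[i - 1] + pz[i + 1] - pz[i];
      if (!in_box(tx, ty, tz)) return false;
      if (occ(tx, ty, tz)) return false;
      mv = {1, i, -1, tx, ty, tz, 0, 0, 0};
      return true;
    }
    int lo = (slot <= 3) ? i : i - 1;
    int hi = lo + 1;
    if (lo < 1 || hi > N - 2) return false;
    int ux = px[hi + 1] - px[lo - 1], uy = py[hi + 1] - py[lo - 1],
        uz = pz[hi + 1] - pz[lo - 1];
    if (ux * ux + uy * uy + uz * uz != 1) return false;
    // chain validity + |u| = 1 force the U shape p[hi] = p[lo] + u
    if (px[hi] - px[lo] != ux || py[hi] - py[lo] != uy ||
        pz[hi] - pz[lo] != uz)
      return false;
    int vx = px[lo] - px[lo - 1], vy = py[lo] - py[lo - 1],
        vz = pz[lo] - pz[lo - 1];
    int r = (slot - 1) % 3;  // 0: 90, 1: 180, 2: 270 degrees about u
    int wx, wy, wz;
    if (r == 1) {
      wx = -vx;
      wy = -vy;
      wz = -vz;
    } else {
      int cx = uy * vz - uz * vy, cy = uz * vx - ux * vz,
          cz = ux * vy - uy * vx;
      if (r == 0) {
        wx = cx;
        wy = cy;
        wz = cz;
      } else {
        wx = -cx;
        wy = -cy;
        wz = -cz;
      }
    }
    int t1x = px[lo - 1] + wx, t1y = py[lo - 1] + wy, t1z = pz[lo - 1] + wz;
    int t2x = t1x + ux, t2y = t1y + uy, t2z = t1z + uz;
    if (!in_box(t1x, t1y, t1z) || !in_box(t2x, t2y, t2z)) return false;
    int o1 = occ(t1x, t1y, t1z);
    if (o1 && o1 - 1 != lo && o1 - 1 != hi) return false;
    int o2 = occ(t2x, t2y, t2z);
    if (o2 && o2 - 1 != lo && o2 - 1 != hi) return false;
    mv = {2, lo, hi, t1x, t1y, t1z, t2x, t2y, t2z};
    return true;
  }

  // Bonded neighbors are never favorable, so the moving pair of a crankshaft
  // cannot contribute a contact with itself and no vacating is needed.
  inline int deltaE(const Move& mv) const {
    if (mv.kind == 1) {
      int i = mv.b1;
      return localC(i, px[i], py[i], pz[i]) - localC(i, mv.x1, mv.y1, mv.z1);
    }
    int lo = mv.b1, hi = mv.b2;
    int oldc = localC(lo, px[lo], py[lo], pz[lo]) +
               localC(hi, px[hi], py[hi], pz[hi]);
    int newc = localC(lo, mv.x1, mv.y1, mv.z1) +
               localC(hi, mv.x2, mv.y2, mv.z2);
    return oldc - newc;
  }

  inline void apply(const Move& mv) {
    setocc(px[mv.b1], py[mv.b1], pz[mv.b1], 0);
    if (mv.kind == 2) setocc(px[mv.b2], py[mv.b2], pz[mv.b2], 0);
    setocc(mv.x1, mv.y1, mv.z1, mv.b1 + 1);
    px[mv.b1] = mv.x1;
    py[mv.b1] = mv.y1;
    pz[mv.b1] = mv.z1;
    if (mv.kind == 2) {
      setocc(mv.x2, mv.y2, mv.z2, mv.b2 + 1);
      px[mv.b2] = mv.x2;
      py[mv.b2] = mv.y2;
      pz[mv.b2] = mv.z2;
    }
  }

  // One attempted elementary move = one MC step; null and rejected proposals
  // leave the chain unchanged but advance time.
  inline bool step(RNG& rng) {
    int i = rng.below(N);
    int K = (i == 0 || i == N - 1) ? 6 : 7;
    int slot = rng.below(K);
    Move mv;
    if (!candidate(i, slot, mv)) return false;
    int dE = deltaE(mv);
    if (dE > 0 && rng.unif() >= expTab[dE]) return false;
    apply(mv);
    E += dE;
    return true;
  }

  inline bool termini_adjacent() const {
    int dx = px[0] - px[N - 1], dy = py[0] - py[N - 1], dz = pz[0] - pz[N - 1];
    return dx * dx + dy * dy + dz * dz == 1;
  }

  IntegerMatrix coords() const {
    IntegerMatrix out(N, 3);
    for (int i = 0; i < N; ++i) {
      out(i, 0) = px[i];
      out(i, 1) = py[i];
      out(i, 2) = pz[i];
    }
    return out;
  }
};

static std::vector<uint8_t> build_fav(int N, const IntegerMatrix& pairs) {
  std::vector<uint8_t> fav((size_t)N * N, 0);
  for (int r = 0; r < pairs.nrow(); ++r) {
    int i = pairs(r, 0), j = pairs(r, 1);
    if (i < 0 || j < 0 || i >= N || j >= N)
      stop("contact pair index out of range");
    fav[(size_t)i * N + j] = 1;
    fav[(size_t)j * N + i] = 1;
  }
  return fav;
}

// Uniform-attempt self-avoiding walk: each step picks one of the six lattice
// directions uniformly and the whole walk is restarted on any collision, so
// accepted walks are exactly uniform over all N-bead SAWs.
// [[Rcpp::export]]
IntegerMatrix cpp_random_coil(int N, double seed, double max_tries) {
  if (N < 2) stop("N must be >= 2");
  if (N > 60) stop("chain length must be <= 60 for the lattice engine");
  RNG rng((uint64_t)seed);
  std::vector<int16_t> grid(1 << 18, 0);
  std::vector<int> x(N), y(N), z(N);
  auto gi = [](int a, int b, int c) {
    return ((a & 63) << 12) | ((b & 63) << 6) | (c & 63);
  };
  double tries = 0;
  while (tries < max_tries) {
    ++tries;
    x[0] = 0; y[0] = 0; z[0] = 0;
    grid[gi(0, 0, 0)] = 1;
    int placed = 1;
    bool ok = true;
    for (int k = 1; k < N; ++k) {
      int d = rng.below(6);
      int nx = x[k - 1] + DX[d], ny = y[k - 1] + DY[d], nz = z[k - 1] + DZ[d];
      if (grid[gi(nx, ny, nz)]) {
        ok = false;
        break;
      }
      x[k] = nx; y[k] = ny; z[k] = nz;
      grid[gi(nx, ny, nz)] = (int16_t)(k + 1);
      ++placed;
    }
    for (int k = 0; k < placed; ++k) grid[gi(x[k], y[k], z[k])] = 0;
    if (ok) {
      IntegerMatrix out(N, 3);
      for (int i = 0; i < N; ++i) {
        out(i, 0) = x[i];
        out(i, 1) = y[i];
        out(i, 2) = z[i];
      }
      return out;
    }
  }
  stop("random_coil: retry budget exhausted after %.0f attempts", max_tries);
}

// Enumerate the legal move candidates at one bead (0-based), one per slot.
// [[Rcpp::export]]
List cpp_move_candidates(IntegerMatrix coords, int bead) {
  Sim sim;
  sim.init(coords, nullptr, false, 0, 0, 0);
  if (bead < 0 || bead >= sim.N) stop("bead index out of range");
  int K = (bead == 0 || bead == sim.N - 1) ? 6 : 7;
  List out;
  for (int slot = 0; slot < K; ++slot) {
    Move mv;
    if (!sim.candidate(bead, slot, mv)) continue;
    IntegerMatrix nc(mv.kind, 3);
    nc(0, 0) = mv.x1; nc(0, 1) = mv.y1; nc(0, 2) = mv.z1;
    IntegerVector beads;
    if (mv.kind == 2) {
      nc(1, 0) = mv.x2; nc(1, 1) = mv.y2; nc(1, 2) = mv.z2;
      beads = IntegerVector::create(mv.b1, mv.b2);
    } else {
      beads = IntegerVector::create(mv.b1);
    }
    std::string kind;
    if (bead == 0 || bead == sim.N - 1) kind = "end-move";
    else if (slot == 0) kind = "corner-flip";
    else kind = "crankshaft";
    out.push_back(List::create(_["slot"] = slot, _["kind"] = kind,
                               _["beads"] = beads, _["new_coords"] = nc));
  }
  return out;
}

// Fixed-temperature Metropolis run; returns energy samples and final state.
// [[Rcpp::export]]
List cpp_run_mc(IntegerMatrix coords, IntegerMatrix native_pairs,
                bool homopolymer, double temperature, double n_steps,
                double sample_stride, double burnin, double seed) {
  Sim sim;
  std::vector<uint8_t> fav;
  if (!homopolymer) {
    fav = build_fav(coords.nrow(), native_pairs);
    sim.init(coords, fav.data(), false, 0, 0, 0);
  } else {
    sim.init(coords, nullptr, false, 0, 0, 0);
  }
  sim.set_temperature(temperature);
  RNG rng((uint64_t)seed);
  long long steps = (long long)n_steps;
  long long stride = (long long)sample_stride;
  long long burn = (long long)burnin;
  std::vector<double> energies;
  long long accepted = 0;
  for (long long s = 1; s <= steps; ++s) {
    if (sim.step(rng)) ++accepted;
    if (stride > 0 && s > burn && s % stride == 0)
      energies.push_back((double)sim.E);
    if ((s & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["energies"] = NumericVector(energies.begin(), energies.end()),
                      _["final"] = sim.coords(),
                      _["acceptance"] = steps > 0 ? (double)accepted / steps : 0.0,
                      _["energy"] = (double)sim.E);
}

// Folding trajectory: run until all native contacts are formed (E = -n_nat)
// or max_steps; optionally record snapshots whose energy lies in
// [snap_lo, snap_hi] every snap_stride steps.
// [[Rcpp::export]]
List cpp_folding_traj(IntegerMatrix start, IntegerMatrix native_pairs,
                      double temperature, double max_steps, double seed,
                      double snap_stride, int snap_lo, int snap_hi,
                      double energy_stride, double max_snapshots) {
  std::vector<uint8_t> fav = build_fav(start.nrow(), native_pairs);
  Sim sim;
  sim.init(start, fav.data(), false, 0, 0, 0);
  sim.set_temperature(temperature);
  RNG rng((uint64_t)seed);
  int target = -native_pairs.nrow();
  long long cap = (long long)max_steps;
  long long sstride = (long long)snap_stride;
  long long estride = (long long)energy_stride;
  long long maxsnap = (long long)max_snapshots;
  std::vector<double> energies;
  std::vector<int> snap_flat;
  std::vector<double> snap_step, snap_E;
  double fpt = NA_REAL;
  bool reached = false;
  if (sim.E == target) {
    fpt = 0;
    reached = true;
  } else {
    for (long long s = 1; s <= cap; ++s) {
      sim.step(rng);
      if (estride > 0 && s % estride == 0) energies.push_back((double)sim.E);
      if (sstride > 0 && s % sstride == 0 && sim.E >= snap_lo &&
          sim.E <= snap_hi && (long long)snap_step.size() < maxsnap) {
        for (int i = 0; i < sim.N; ++i) {
          snap_flat.push_back(sim.px[i]);
          snap_flat.push_back(sim.py[i]);
          snap_flat.push_back(sim.pz[i]);
        }
        snap_step.push_back((double)s);
        snap_E.push_back((double)sim.E);
      }
      if (sim.E == target) {
        fpt = (double)s;
        reached = true;
        break;
      }
      if ((s & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }
  }
  int nsnap = (int)snap_step.size();
  IntegerMatrix snaps(nsnap, 3 * sim.N);
  for (int r = 0; r < nsnap; ++r)
    for (int c = 0; c < 3 * sim.N; ++c)
      snaps(r, c) = snap_flat[(size_t)r * 3 * sim.N + c];
  return List::create(
      _["fpt"] = fpt, _["reached"] = reached,
      _["energies"] = NumericVector(energies.begin(), energies.end()),
      _["snap_step"] = NumericVector(snap_step.begin(), snap_step.end()),
      _["snap_energy"] = NumericVector(snap_E.begin(), snap_E.end()),
      _["snapshots"] = snaps, _["final"] = sim.coords());
}

// Pfold trials: from `start`, count trajectories that reach the native state
// (all contacts) before dropping to <= unfold_contacts formed contacts.
// [[Rcpp::export]]
IntegerVector cpp_pfold(IntegerMatrix start, IntegerMatrix native_pairs,
                        double temperature, int n_trials, int unfold_contacts,
                        double max_steps, double seed) {
  std::vector<uint8_t> fav = build_fav(start.nrow(), native_pairs);
  int target = -native_pairs.nrow();
  long long cap = (long long)max_steps;
  RNG seeder((uint64_t)seed);
  int nfold = 0, nunfold = 0, nindet = 0;
  Sim sim;
  for (int t = 0; t < n_trials; ++t) {
    uint64_t s = seeder.next();
    RNG rng(s);
    sim.init(start, fav.data(), false, 0, 0, 0);
    sim.set_temperature(temperature);
    if (sim.E == target) {
      ++nfold;
      continue;
    }
    if (-sim.E <= unfold_contacts) {
      ++nunfold;
      continue;
    }
    bool done = false;
    for (long long k = 1; k <= cap; ++k) {
      sim.step(rng);
      if (sim.E == target) {
        ++nfold;
        done = true;
        break;
      }
      if (-sim.E <= unfold_contacts) {
        ++nunfold;
        done = true;
        break;
      }
      if ((k & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }
    if (!done) ++nindet;
  }
  return IntegerVector::create(nfold, nunfold, nindet);
}

// Replica-exchange MC.  All replicas start from `start`; adjacent-pair swaps
// alternate parity between rounds; one energy sample per temperature per
// round after burn-in.
// [[Rcpp::export]]
List cpp_parallel_tempering(IntegerMatrix start, IntegerMatrix native_pairs,
                            NumericVector temps, double steps_per_round,
                            int n_rounds, int burnin_rounds, double seed) {
  int nT = temps.size();
  if (nT < 2) stop("need at least two temperatures");
  std::vector<uint8_t> fav = build_fav(start.nrow(), native_pairs);
  std::vector<Sim> sims(nT);
  for (int t = 0; t < nT; ++t) {
    sims[t].init(start, fav.data(), false, 0, 0, 0);
    sims[t].set_temperature(temps[t]);
  }
  RNG rng((uint64_t)seed);
  long long spr = (long long)steps_per_round;
  int nsamp = n_rounds - burnin_rounds;
  if (nsamp <= 0) stop("n_rounds must exceed burnin_rounds");
  NumericMatrix samples(nsamp, nT);
  NumericVector att(nT - 1), acc(nT - 1);
  for (int round = 0; round < n_rounds; ++round) {
    for (int t = 0; t < nT; ++t)
      for (long long s = 0; s < spr; ++s) sims[t].step(rng);
    int parity = round & 1;
    for (int i = parity; i + 1 < nT; i += 2) {
      att[i] += 1;
      double delta = (1.0 / temps[i] - 1.0 / temps[i + 1]) *
                     ((double)sims[i].E - (double)sims[i + 1].E);
      if (delta >= 0 || rng.unif() < std::exp(delta)) {
        acc[i] += 1;
        std::swap(sims[i].px, sims[i + 1].px);
        std::swap(sims[i].py, sims[i + 1].py);
        std::swap(sims[i].pz, sims[i + 1].pz);
        std::swap(sims[i].grid, sims[i + 1].grid);
        std::swap(sims[i].E, sims[i + 1].E);
      }
    }
    if (round >= burnin_rounds)
      for (int t = 0; t < nT; ++t) samples(round - burnin_rounds, t) = sims[t].E;
    Rcpp::checkUserInterrupt();
  }
  List finals(nT);
  for (int t = 0; t < nT; ++t) finals[t] = sims[t].coords();
  NumericVector swap_rate(nT - 1);
  for (int i = 0; i < nT - 1; ++i)
    swap_rate[i] = att[i] > 0 ? acc[i] / att[i] : NA_REAL;
  return List::create(_["samples"] = samples, _["swap_acceptance"] = swap_rate,
                      _["finals"] = finals);
}

// Homopolymer collapse by simulated annealing inside a confining box, then a
// fixed-temperature search phase that waits for a ground-state visit with
// adjacent termini whose bounding box is the target cuboid.
static bool extents_match(const Sim& sim, const IntegerVector& box) {
  int lo[3] = {sim.px[0], sim.py[0], sim.pz[0]};
  int hi[3] = {sim.px[0], sim.py[0], sim.pz[0]};
  for (int i = 1; i < sim.N; ++i) {
    int c[3] = {sim.px[i], sim.py[i], sim.pz[i]};
    for (int d = 0; d < 3; ++d) {
      if (c[d] < lo[d]) lo[d] = c[d];
      if (c[d] > hi[d]) hi[d] = c[d];
    }
  }
  int ext[3];
  for (int d = 0; d < 3; ++d) ext[d] = hi[d] - lo[d] + 1;
  std::sort(ext, ext + 3);
  int tb[3] = {box[0], box[1], box[2]};
  std::sort(tb, tb + 3);
  return ext[0] == tb[0] && ext[1] == tb[1] && ext[2] == tb[2];
}

// [[Rcpp::export]]
List cpp_collapse(IntegerMatrix start, IntegerVector confine,
                  IntegerVector target_box, NumericVector anneal_temps,
                  double steps_per_temp, int target_contacts, double t_search,
                  double search_steps, double seed, int termini_weight) {
  Sim sim;
  sim.tw = termini_weight < 1 ? 1 : termini_weight;
  sim.init(start, nullptr, true, confine[0], confine[1], confine[2]);
  RNG rng((uint64_t)seed);
  // with the terminus-terminus contact up-weighted, the target energy of a
  // maximally compact, termini-adjacent state is -(contacts - 1 + weight)
  int target = -(target_contacts - 1 + sim.tw);
  long long spt = (long long)steps_per_temp;
  double steps_used = 0;
  bool reached_compact = false;
  for (int ti = 0; ti < anneal_temps.size(); ++ti) {
    sim.set_temperature(anneal_temps[ti]);
    for (long long s = 0; s < spt; ++s) {
      sim.step(rng);
      ++steps_used;
      if (sim.E <= target + sim.tw - 1) reached_compact = true;
      if (sim.E == target && sim.termini_adjacent() &&
          extents_match(sim, target_box))
        return List::create(_["success"] = true, _["coords"] = sim.coords(),
                            _["contacts"] = target_contacts,
                            _["steps_used"] = steps_used,
                            _["reached_compact"] = true);
      if (((long long)steps_used & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }
  }
  sim.set_temperature(t_search);
  long long sst = (long long)search_steps;
  for (long long s = 0; s < sst; ++s) {
    sim.step(rng);
    ++steps_used;
    if (sim.E <= target + sim.tw - 1) reached_compact = true;
    if (sim.E == target && sim.termini_adjacent() &&
        extents_match(sim, target_box))
      return List::create(_["success"] = true, _["coords"] = sim.coords(),
                          _["contacts"] = target_contacts,
                          _["steps_used"] = steps_used,
                          _["reached_compact"] = true);
    if (((long long)steps_used & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["success"] = false, _["coords"] = sim.coords(),
                      _["contacts"] = -sim.E, _["steps_used"] = steps_used,
                      _["reached_compact"] = reached_compact);
}

// Exhaustive enumeration of all N-bead self-avoiding walks starting at the
// origin; returns counts of walks by number of favorable contacts.  Exact
// density of states for small chains (N <= 10).
// [[Rcpp::export]]
NumericVector cpp_enumerate_saw_energies(int N, IntegerMatrix native_pairs,
                                         bool homopolymer) {
  if (N < 2 || N > 10) stop("enumeration supported for 2 <= N <= 10");
  std::vector<uint8_t> fav;
  const uint8_t* favp = nullptr;
  if (!homopolymer) {
    fav = build_fav(N, native_pairs);
    favp = fav.data();
  }
  int maxc = homopolymer ? (N * N) : native_pairs.nrow();
  std::vector<double> counts(maxc + 1, 0.0);
  std::vector<int16_t> grid(1 << 18, 0);
  std::vector<int> x(N), y(N), z(N), gained(N, 0);
  auto gi = [](int a, int b, int c) {
    return ((a & 63) << 12) | ((b & 63) << 6) | (c & 63);
  };
  auto favtest = [&](int a, int b) {
    int d = a - b;
    if (d < 0) d = -d;
    if (d < 2) return false;
    return favp ? favp[a * N + b] != 0 : true;
  };
  x[0] = y[0] = z[0] = 0;
  grid[gi(0, 0, 0)] = 1;
  std::function<void(int, int)> rec = [&](int depth, int contacts) {
    if (depth == N) {
      counts[contacts] += 1;
      return;
    }
    for (int d = 0; d < 6; ++d) {
      int nx = x[depth - 1] + DX[d], ny = y[depth - 1] + DY[d],
          nz = z[depth - 1] + DZ[d];
      if (grid[gi(nx, ny, nz)]) continue;
      int g = 0;
      for (int dd = 0; dd < 6; ++dd) {
        int o = grid[gi(nx + DX[dd], ny + DY[dd], nz + DZ[dd])];
        if (o && favtest(depth, o - 1)) ++g;
      }
      x[depth] = nx;
      y[depth] = ny;
      z[depth] = nz;
      grid[gi(nx, ny, nz)] = (int16_t)(depth + 1);
      rec(depth + 1, contacts + g);
      grid[gi(nx, ny, nz)] = 0;
    }
  };
  rec(1, 0);
  (void)gained;
  return NumericVector(counts.begin(), counts.end());
}
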