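// Dynamic Loop lattice engine.
//
// Single-site variant of the bond-fluctuation model on a cubic lattice with
// periodic boundaries: monomer positions are stored UNWRAPPED (observables
// need real-space geometry), excluded volume is enforced on WRAPPED sites.
// Allowed bond vectors are all displacements with components in {-1, 0, +1}
// except the null vector (lengths 1, sqrt(2), sqrt(3)); the loop-formation
// cutoff equals the maximum bond length sqrt(3), i.e. Chebyshev distance 1.
//
// All stochastic draws consume R's RNG in a fixed order per trial move:
// monomer index, direction, then (if a move was accepted, loops are enabled
// and the monomer is unbonded with at least one eligible neighbour)
// candidate index, formation coin, Poisson lifetime.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdlib>
#include <algorithm>

using namespace Rcpp;

static inline int wrap_coord(int a, int L) {
  int r = a % L;
  return r < 0 ? r + L : r;
}

namespace {

struct Engine {
  int N, L;
  std::vector<int> px, py, pz;                 // unwrapped positions
  std::unordered_map<long long, int> occ;      // wrapped site -> monomer (0-based)
  std::vector<int> partner;                    // loop partner (0-based) or -1
  std::vector<double> expiry;                  // expiry MCS of the active bond
  double clock_;

  long long site_key(int x, int y, int z) const {
    return (long long)wrap_coord(x, L) +
           (long long)L * ((long long)wrap_coord(y, L) +
                           (long long)L * wrap_coord(z, L));
  }

  void build_occupancy() {
    occ.clear();
    occ.reserve((size_t)(2 * N));
    for (int i = 0; i < N; ++i) {
      long long k = site_key(px[i], py[i], pz[i]);
      if (occ.count(k))
        stop("invalid state: two monomers occupy one lattice site");
      occ[k] = i;
    }
  }

  // a displacement is an allowed bond vector iff nonzero with Chebyshev norm 1
  static bool vec_ok(int dx, int dy, int dz) {
    if (dx == 0 && dy == 0 && dz == 0) return false;
    return std::abs(dx) <= 1 && std::abs(dy) <= 1 && std::abs(dz) <= 1;
  }

  bool bond_ok_from(int x, int y, int z, int j) const {
    return vec_ok(x - px[j], y - py[j], z - pz[j]);
  }
};

const int DX[6] = { 1, -1, 0, 0, 0, 0 };
const int DY[6] = { 0, 0, 1, -1, 0, 0 };
const int DZ[6] = { 0, 0, 0, 0, 1, -1 };

Engine load_engine(const IntegerMatrix& positions,
                   const IntegerVector& loop_i, const IntegerVector& loop_j,
                   const NumericVector& loop_expiry,
                   double mcs_clock, int L) {
  Engine S;
  S.N = positions.nrow();
  S.L = L;
  if (S.N < 2) stop("need at least 2 monomers");
  if (L < 2) stop("lattice size L must be >= 2");
  S.px.resize(S.N); S.py.resize(S.N); S.pz.resize(S.N);
  for (int i = 0; i < S.N; ++i) {
    S.px[i] = positions(i, 0);
    S.py[i] = positions(i, 1);
    S.pz[i] = positions(i, 2);
  }
  S.partner.assign(S.N, -1);
  S.expiry.assign(S.N, 0.0);
  int nb = loop_i.size();
  if (loop_j.size() != nb || loop_expiry.size() != nb)
    stop("loop bond vectors must have equal length");
  for (int b = 0; b < nb; ++b) {
    int i = loop_i[b] - 1, j = loop_j[b] - 1;  // R side is 1-based
    if (i < 0 || j < 0 || i >= S.N || j >= S.N || i == j)
      stop("loop bond index out of range");
    if (S.partner[i] != -1 || S.partner[j] != -1)
      stop("invalid state: monomer holds more than one loop bond");
    S.partner[i] = j; S.partner[j] = i;
    S.expiry[i] = loop_expiry[b]; S.expiry[j] = loop_expiry[b];
  }
  S.clock_ = mcs_clock;
  S.build_occupancy();
  return S;
}

IntegerMatrix dump_positions(const Engine& S) {
  IntegerMatrix out(S.N, 3);
  for (int i = 0; i < S.N; ++i) {
    out(i, 0) = S.px[i]; out(i, 1) = S.py[i]; out(i, 2) = S.pz[i];
  }
  return out;
}

List dump_loops(const Engine& S) {
  std::vector<int> li, lj;
  std::vector<double> le;
  for (int i = 0; i < S.N; ++i) {
    int j = S.partner[i];
    if (j > i) { li.push_back(i + 1); lj.push_back(j + 1); le.push_back(S.expiry[i]); }
  }
  return List::create(_["i"] = wrap(li), _["j"] = wrap(lj), _["expiry"] = wrap(le));
}

inline int unif_index(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

bool try_move(Engine& S, int m, int dir) {
  int nx = S.px[m] + DX[dir], ny = S.py[m] + DY[dir], nz = S.pz[m] + DZ[dir];
  long long nk = S.site_key(nx, ny, nz);
  if (S.occ.count(nk)) return false;                  // excluded volume
  if (m > 0 && !S.bond_ok_from(nx, ny, nz, m - 1)) return false;
  if (m < S.N - 1 && !S.bond_ok_from(nx, ny, nz, m + 1)) return false;
  if (S.partner[m] >= 0 && !S.bond_ok_from(nx, ny, nz, S.partner[m])) return false;
  S.occ.erase(S.site_key(S.px[m], S.py[m], S.pz[m]));
  S.occ[nk] = m;
  S.px[m] = nx; S.py[m] = ny; S.pz[m] = nz;
  return true;
}

// unbonded non-backbone monomers within the cutoff of m (unwrapped distance,
// so periodic images resolved through the occupancy map are rejected)
int gather_candidates(const Engine& S, int m, int* cand) {
  int k = 0;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        auto it = S.occ.find(S.site_key(S.px[m] + dx, S.py[m] + dy, S.pz[m] + dz));
        if (it == S.occ.end()) continue;
        int j = it->second;
        if (S.px[j] - S.px[m] != dx || S.py[j] - S.py[m] != dy ||
            S.pz[j] - S.pz[m] != dz) continue;      // periodic image
        if (std::abs(j - m) < 2) continue;          // backbone neighbours/self
        if (S.partner[j] >= 0) continue;
        cand[k++] = j;
      }
  return k;
}

void one_mcs(Engine& S, const std::vector<double>& aff, double mean_lifetime,
             bool loops_enabled, long long& trials, long long& accepts) {
  int cand[26];
  for (int t = 0; t < S.N; ++t) {
    int m = unif_index(S.N);
    int dir = unif_index(6);
    ++trials;
    if (!try_move(S, m, dir)) continue;
    ++accepts;
    if (!loops_enabled || S.partner[m] >= 0) continue;
    int K = gather_candidates(S, m, cand);
    if (K == 0) continue;
    int j = cand[unif_index(K)];
    double p = std::sqrt(aff[m] * aff[j]);
    if (unif_rand() < p) {
      double e = S.clock_ + R::rpois(mean_lifetime);
      S.partner[m] = j; S.partner[j] = m;
      S.expiry[m] = e; S.expiry[j] = e;
    }
  }
  for (int i = 0; i < S.N; ++i) {           // inclusive expiry, once per MCS
    int j = S.partner[i];
    if (j > i && S.expiry[i] <= S.clock_) { S.partner[i] = -1; S.partner[j] = -1; }
  }
  S.clock_ += 1.0;
}

double rg2_of(const Engine& S) {
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < S.N; ++i) { cx += S.px[i]; cy += S.py[i]; cz += S.pz[i]; }
  cx /= S.N; cy /= S.N; cz /= S.N;
  double s = 0;
  for (int i = 0; i < S.N; ++i) {
    double dx = S.px[i] - cx, dy = S.py[i] - cy, dz = S.pz[i] - cz;
    s += dx * dx + dy * dy + dz * dz;
  }
  return s / S.N;
}

} // namespace

// [[Rcpp::export]]
List cpp_run(IntegerMatrix positions, IntegerVector loop_i, IntegerVector loop_j,
             NumericVector loop_expiry, double mcs_clock, int n_mcs, int L,
             NumericVector affinities, double mean_lifetime, bool loops_enabled,
             int snapshot_every = 0, int rg_every = 0, int traj_every = 0,
             int max_traj_frames = 0) {
  Engine S = load_engine(positions, loop_i, loop_j, loop_expiry, mcs_clock, L);
  if ((int)affinities.size() != S.N)
    stop("affinities must have one entry per monomer");
  for (double a : affinities)
    if (!(a >= 0.0 && a <= 1.0)) stop("affinities must lie in [0, 1]");
  if (mean_lifetime < 0) stop("mean_lifetime must be >= 0");
  std::vector<double> aff(affinities.begin(), affinities.end());

  long long trials = 0, accepts = 0;
  List snapshots; std::vector<double> snap_mcs;
  std::vector<double> rg_mcs, rg_val;
  List traj; std::vector<double> traj_mcs;

  for (int s = 0; s < n_mcs; ++s) {
    one_mcs(S, aff, mean_lifetime, loops_enabled, trials, accepts);
    int done = s + 1;
    if (rg_every > 0 && done % rg_every == 0) {
      rg_mcs.push_back(S.clock_);
      rg_val.push_back(rg2_of(S));
    }
    if (snapshot_every > 0 && done % snapshot_every == 0) {
      snapshots.push_back(List::create(
        _["mcs"] = S.clock_, _["positions"] = dump_positions(S),
        _["loops"] = dump_loops(S)));
      snap_mcs.push_back(S.clock_);
    }
    if (traj_every > 0 && done % traj_every == 0 &&
        (max_traj_frames <= 0 || (int)traj_mcs.size() < max_traj_frames)) {
      traj.push_back(dump_positions(S));
      traj_mcs.push_back(S.clock_);
    }
    if (done % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["positions"] = dump_positions(S), _["loops"] = dump_loops(S),
    _["mcs_clock"] = S.clock_, _["trials"] = (double)trials,
    _["accepts"] = (double)accepts, _["snapshots"] = snapshots,
    _["snapshot_mcs"] = wrap(snap_mcs), _["rg_mcs"] = wrap(rg_mcs),
    _["rg2"] = wrap(rg_val), _["trajectory"] = traj,
    _["trajectory_mcs"] = wrap(traj_mcs));
}

// Single trial move; monomer/direction may be forced (1-based / 1..6) or
// drawn from the RNG when 0.
// [[Rcpp::export]]
List cpp_try_move(IntegerMatrix positions, IntegerVector loop_i, IntegerVector loop_j,
                  NumericVector loop_expiry, double mcs_clock, int L,
                  int monomer = 0, int direction = 0) {
  Engine S = load_engine(positions, loop_i, loop_j, loop_expiry, mcs_clock, L);
  int m = monomer > 0 ? monomer - 1 : unif_index(S.N);
  int dir = direction > 0 ? direction - 1 : unif_index(6);
  if (m < 0 || m >= S.N) stop("monomer index out of range");
  if (dir < 0 || dir >= 6) stop("direction must be in 1..6");
  bool acc = try_move(S, m, dir);
  return List::create(_["accepted"] = acc, _["moved_index"] = m + 1,
                      _["positions"] = dump_positions(S));
}

// [[Rcpp::export]]
IntegerVector cpp_neighbors_within_cutoff(IntegerMatrix positions, int i, int L) {
  Engine S = load_engine(positions, IntegerVector(0), IntegerVector(0),
                         NumericVector(0), 0.0, L);
  if (i < 1 || i > S.N) stop("monomer index out of range");
  int m = i - 1;
  std::vector<int> out;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        auto it = S.occ.find(S.site_key(S.px[m] + dx, S.py[m] + dy, S.pz[m] + dz));
        if (it == S.occ.end()) continue;
        int j = it->second;
        if (S.px[j] - S.px[m] != dx || S.py[j] - S.py[m] != dy ||
            S.pz[j] - S.pz[m] != dz) continue;
        if (std::abs(j - m) == 1) continue;        // backbone neighbours excluded
        out.push_back(j + 1);
      }
  std::sort(out.begin(), out.end());
  return wrap(out);
}

// [[Rcpp::export]]
CharacterVector cpp_validate_state(IntegerMatrix positions, IntegerVector loop_i,
                                   IntegerVector loop_j, NumericVector loop_expiry,
                                   double mcs_clock, int L) {
  std::vector<std::string> bad;
  int N = positions.nrow();
  if (N < 2) bad.push_back("chain has fewer than 2 monomers");
  // occupancy: duplicate wrapped sites
  std::unordered_map<long long, int> occ;
  for (int i = 0; i < N; ++i) {
    long long k = (long long)wrap_coord(positions(i, 0), L) +
                  (long long)L * ((long long)wrap_coord(positions(i, 1), L) +
                                  (long long)L * wrap_coord(positions(i, 2), L));
    auto it = occ.find(k);
    if (it != occ.end())
      bad.push_back("overlap: monomers " + std::to_string(it->second + 1) + " and " +
                    std::to_string(i + 1) + " share a lattice site");
    else occ[k] = i;
  }
  for (int i = 0; i + 1 < N; ++i) {
    int dx = positions(i + 1, 0) - positions(i, 0);
    int dy = positions(i + 1, 1) - positions(i, 1);
    int dz = positions(i + 1, 2) - positions(i, 2);
    if (!Engine::vec_ok(dx, dy, dz))
      bad.push_back("backbone bond " + std::to_string(i + 1) + "-" +
                    std::to_string(i + 2) + " is not an allowed bond vector");
  }
  std::vector<int> deg(N, 0);
  for (int b = 0; b < loop_i.size(); ++b) {
    int i = loop_i[b], j = loop_j[b];
    if (i < 1 || j < 1 || i > N || j > N) {
      bad.push_back("loop bond " + std::to_string(b + 1) + " has out-of-range monomer");
      continue;
    }
    if (std::abs(i - j) < 2)
      bad.push_back("loop bond (" + std::to_string(i) + "," + std::to_string(j) +
                    ") joins backbone neighbours or a monomer to itself");
    int dx = positions(j - 1, 0) - positions(i - 1, 0);
    int dy = positions(j - 1, 1) - positions(i - 1, 1);
    int dz = positions(j - 1, 2) - positions(i - 1, 2);
    if (!Engine::vec_ok(dx, dy, dz))
      bad.push_back("loop bond (" + std::to_string(i) + "," + std::to_string(j) +
                    ") stretched beyond the cutoff");
    if (b < loop_expiry.size() && loop_expiry[b] < mcs_clock)
      bad.push_back("loop bond (" + std::to_string(i) + "," + std::to_string(j) +
                    ") is past its expiry (dangling bond)");
    deg[i - 1]++; deg[j - 1]++;
  }
  for (int i = 0; i < N; ++i)
    if (deg[i] > 1)
      bad.push_back("monomer " + std::to_string(i + 1) + " holds more than one loop bond");
  return wrap(bad);
}

// Biased self-avoiding growth over the 26 allowed bond vectors; the loop-free
// equilibration run removes the residual growth bias.
// [[Rcpp::export]]
IntegerMatrix cpp_init_chain(int N, int L, int max_restarts = 200) {
  if (N < 2) stop("need at least 2 monomers");
  if (L < 2) stop("lattice size L must be >= 2");
  if ((double)N > 0.5 * (double)L * L * L)
    stop("chain does not fit the lattice; increase L");
  for (int attempt = 0; attempt < max_restarts; ++attempt) {
    std::unordered_map<long long, int> occ;
    std::vector<int> px(N), py(N), pz(N);
    auto key = [&](int x, int y, int z) {
      return (long long)wrap_coord(x, L) +
             (long long)L * ((long long)wrap_coord(y, L) +
                             (long long)L * wrap_coord(z, L));
    };
    px[0] = unif_index(L); py[0] = unif_index(L); pz[0] = unif_index(L);
    occ[key(px[0], py[0], pz[0])] = 0;
    bool ok = true;
    for (int i = 1; i < N; ++i) {
      int fx[26], fy[26], fz[26], nfree = 0;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x = px[i - 1] + dx, y = py[i - 1] + dy, z = pz[i - 1] + dz;
            if (!occ.count(key(x, y, z))) {
              fx[nfree] = x; fy[nfree] = y; fz[nfree] = z; ++nfree;
            }
          }
      if (nfree == 0) { ok = false; break; }
      int c = unif_index(nfree);
      px[i] = fx[c]; py[i] = fy[c]; pz[i] = fz[c];
      occ[key(px[i], py[i], pz[i])] = i;
    }
    if (ok) {
      IntegerMatrix out(N, 3);
      for (int i = 0; i < N; ++i) { out(i, 0) = px[i]; out(i, 1) = py[i]; out(i, 2) = pz[i]; }
      return out;
    }
  }
  stop("failed to place the chain after repeated attempts; increase L");
}

// Frozen-contact harness: two bonded-eligible monomers held at unit distance;
// repeatedly runs the engine's formation path (candidate pick, coin, Poisson
// lifetime) and returns the realised lifetimes of n_bonds bonds.
// [[Rcpp::export]]
NumericVector cpp_lifetime_harness(int n_bonds, double mean_lifetime, double p) {
  if (n_bonds < 1) stop("n_bonds must be positive");
  if (mean_lifetime < 0) stop("mean_lifetime must be >= 0");
  if (!(p >= 0.0 && p <= 1.0)) stop("p must lie in [0, 1]");
  NumericVector out(n_bonds);
  int got = 0;
  long long guard = 0;
  while (got < n_bonds) {
    if (++guard > (long long)(10.0 * n_bonds / (p > 1e-6 ? p : 1e-6)) + 1000000LL)
      stop("harness failed to form bonds (p too small?)");
    // one candidate in range -> uniform pick is a single draw, then the coin
    (void)unif_index(1);
    if (unif_rand() < p) {
      double life = R::rpois(mean_lifetime);
      out[got++] = life;   // inclusive expiry: bond lives exactly `life` MCS
    }
    if (guard % 100000 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
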