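// Core RGB (Reference-Gamble-Birth) update loop.
//
// One elementary update:
//   1. Gamble drawn uniformly from all N nodes.
//   2. Reference drawn uniformly from the Gamble's neighbourhood.
//   3. With probability D[sp(G), sp(R)] the Gamble dies.
//   4. On death, a Birth is drawn uniformly (independently, with
//      replacement) from the neighbourhood and its species fills the spot.
// Time advances by one virtual unit per update whether or not a death
// occurs; callers convert updates to rescaled time via updates / (N * s).
//
// The RNG is a self-contained xoshiro256++ seeded through splitmix64 so
// trajectories are bit-reproducible for a given (state, params, seed)
// independently of R's RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static inline uint64_t splitmix64_next(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256 {
  uint64_t s[4];
  explicit Xoshiro256(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64_next(x);
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform integer in [0, n); bias O(n / 2^53) is negligible for n < 2^31
  inline int below(int n) {
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

// Network kinds understood by the fast loop.
enum NetKind { NET_FC = 0, NET_GRID = 1, NET_CSR = 2 };

struct Engine {
  int kind;
  int N;
  int L;        // grid side (NET_GRID)
  int degree;   // 4 (von Neumann) or 8 (Moore) for NET_GRID
  const int *adj;      // CSR neighbour ids (NET_CSR), 0-based
  const int *adj_ptr;  // CSR offsets, length N + 1
  double D[9];         // death matrix, row-major D[sg * 3 + sr]
  std::vector<int> sp; // species label per node, 0/1/2
  long long cnt[3];
  Xoshiro256 rng;

  Engine(const IntegerVector &species0, const NumericMatrix &Dm,
         int kind_, int L_, int degree_,
         const IntegerVector &csr_adj, const IntegerVector &csr_ptr,
         double seed)
      : kind(kind_), N(species0.size()), L(L_), degree(degree_),
        adj(csr_adj.size() ? &csr_adj[0] : nullptr),
        adj_ptr(csr_ptr.size() ? &csr_ptr[0] : nullptr),
        rng((uint64_t)seed) {
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) D[i * 3 + j] = Dm(i, j);
    sp.assign(species0.begin(), species0.end());
    cnt[0] = cnt[1] = cnt[2] = 0;
    for (int i = 0; i < N; ++i) {
      if (sp[i] < 0 || sp[i] > 2) stop("species labels must be 0, 1 or 2");
      ++cnt[sp[i]];
    }
  }

  inline int neighbour(int i) {
    switch (kind) {
    case NET_FC: {
      int j = rng.below(N - 1);
      return j >= i ? j + 1 : j;
    }
    case NET_GRID: {
      static const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
      static const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
      int k = rng.below(degree);
      int r = i / L + dr[k], c = i % L + dc[k];
      if (r < 0) r += L; else if (r >= L) r -= L;
      if (c < 0) c += L; else if (c >= L) c -= L;
      return r * L + c;
    }
    default: {
      int a = adj_ptr[i], d = adj_ptr[i + 1] - a;
      return adj[a + rng.below(d)];
    }
    }
  }

  // One RGB update; returns the species that just went extinct, or -1.
  inline int step() {
    int g = rng.below(N);
    int sg = sp[g];
    int sr = sp[neighbour(g)];
    if (rng.unif() < D[sg * 3 + sr]) {
      int sb = sp[neighbour(g)];
      if (sb != sg) {
        sp[g] = sb;
        --cnt[sg];
        ++cnt[sb];
        if (cnt[sg] == 0) return sg;
      }
    }
    return -1;
  }
};

// [[Rcpp::export]]
List cpp_simulate(IntegerVector species0, NumericMatrix D,
                  int net_kind, int L, int degree,
                  IntegerVector csr_adj, IntegerVector csr_ptr,
                  double seed, double max_updates,
                  bool stop_at_extinction,
                  double sample_every,
                  NumericVector snap_at,
                  bool keep_state) {
  Engine e(species0, D, net_kind, L, degree, csr_adj, csr_ptr, seed);
  const long long cap = (long long)max_updates;

  // already-extinct initial state: report without stepping
  int first_extinct = -1;
  for (int s = 0; s < 3; ++s)
    if (e.cnt[s] == 0 && first_extinct < 0) first_extinct = s;

  std::vector<double> traj_t;
  std::vector<long long> traj_c;
  const long long samp = sample_every > 0 ? (long long)sample_every : 0;
  if (samp > 0) {
    traj_t.push_back(0.0);
    for (int s = 0; s < 3; ++s) traj_c.push_back(e.cnt[s]);
  }

  const int n_snap = snap_at.size();
  IntegerMatrix snaps(n_snap > 0 ? n_snap : 0, n_snap > 0 ? e.N : 0);
  int snap_done = 0;

  long long upd = 0;
  bool extinct = first_extinct >= 0;
  if (!(stop_at_extinction && extinct)) {
    while (upd < cap) {
      ++upd;
      int gone = e.step();
      if (gone >= 0 && !extinct) {
        extinct = true;
        first_extinct = gone;
      }
      if (samp > 0 && upd % samp == 0) {
        traj_t.push_back((double)upd);
        for (int s = 0; s < 3; ++s) traj_c.push_back(e.cnt[s]);
      }
      while (snap_done < n_snap && (double)upd >= snap_at[snap_done]) {
        for (int i = 0; i < e.N; ++i) snaps(snap_done, i) = e.sp[i];
        ++snap_done;
      }
      if (extinct && stop_at_extinction) break;
    }
  }

  NumericMatrix traj;
  if (samp > 0) {
    int nr = traj_t.size();
    traj = NumericMatrix(nr, 4);
    for (int r = 0; r < nr; ++r) {
      traj(r, 0) = traj_t[r];
      for (int s = 0; s < 3; ++s) traj(r, s + 1) = (double)traj_c[r * 3 + s];
    }
  }

  List out = List::create(
      _["updates"] = (double)upd,
      _["extinct"] = extinct,
      _["first_extinct"] = first_extinct,
      _["censored"] = !extinct,
      _["counts"] = NumericVector::create((double)e.cnt[0], (double)e.cnt[1],
                                          (double)e.cnt[2]),
      _["snap_taken"] = snap_done);
  if (keep_state)
    out["species"] = IntegerVector(e.sp.begin(), e.sp.end());
  if (samp > 0) out["trajectory"] = traj;
  if (n_snap > 0) out["snapshots"] = snaps;
  return out;
}

// K independent single updates from the same initial state; tallies death
// events by (gamble species, birth species).  Non-death updates are the
// remainder K - sum(tally).
// [[Rcpp::export]]
List cpp_one_step_tally(IntegerVector species0, NumericMatrix D,
                        int net_kind, int L, int degree,
                        IntegerVector csr_adj, IntegerVector csr_ptr,
                        double seed, int K) {
  Engine e(species0, D, net_kind, L, degree, csr_adj, csr_ptr, seed);
  IntegerMatrix tally(3, 3);
  for (int k = 0; k < K; ++k) {
    int g = e.rng.below(e.N);
    int sg = e.sp[g];
    int sr = e.sp[e.neighbour(g)];
    if (e.rng.unif() < e.D[sg * 3 + sr]) {
      int sb = e.sp[e.neighbour(g)];
      tally(sg, sb) += 1;
    }
  }
  return List::create(_["deaths"] = tally, _["n"] = K);
}
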