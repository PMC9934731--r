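#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ with splitmix64 seeding. Each replicate r gets its own
// stream seeded deterministically from (base_seed, r), so replicates are
// independent of each other and individually reproducible, and results do not
// depend on R's RNG state.

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform double in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform integer in [0, m); modulo bias is < 2^-50 for the m used here
  inline int below(int m) { return (int)(next() % (uint64_t)m); }
};

static inline uint64_t replicate_seed(uint64_t base, uint64_t r) {
  uint64_t x = base ^ (0x9E3779B97F4A7C15ULL * (r + 1));
  return splitmix64(x);
}

// ---------------------------------------------------------------------------
// Rule bytecode: postfix pairs (op, arg) per node, concatenated, with
// node_off giving the pair offset of each node's code (length n + 1).
//   op 0: push constant arg (0/1)
//   op 1: push state[arg]
//   op 2: logical NOT of top
//   op 3: AND of top `arg` entries
//   op 4: OR of top `arg` entries

static inline int eval_rule(const int *code, int from, int to,
                            const std::vector<int> &state, int *stack) {
  int sp = 0;
  for (int k = from; k < to; ++k) {
    int op = code[2 * k], arg = code[2 * k + 1];
    switch (op) {
    case 0: stack[sp++] = arg; break;
    case 1: stack[sp++] = state[arg]; break;
    case 2: stack[sp - 1] = 1 - stack[sp - 1]; break;
    case 3: {
      int v = 1;
      for (int j = sp - arg; j < sp; ++j) v &= stack[j];
      sp -= arg; stack[sp++] = v; break;
    }
    case 4: {
      int v = 0;
      for (int j = sp - arg; j < sp; ++j) v |= stack[j];
      sp -= arg; stack[sp++] = v; break;
    }
    default: Rcpp::stop("corrupt rule bytecode");
    }
  }
  return stack[0];
}

// The elementary stochastic update: rule satisfied & node OFF -> ON with
// probability p_a; rule unsatisfied & node ON -> OFF with probability p_d;
// otherwise no event. One uniform draw is consumed per node per iteration.
static inline int update_bit(int f, int x, double pa, double pd, double u) {
  if (f == x) return x;
  if (f == 1) return (u < pa) ? 1 : 0;
  return (u < pd) ? 0 : 1;
}

// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(IntegerVector code, IntegerVector node_off,
                  NumericVector pa, NumericVector pd, IntegerVector init,
                  int horizon, int replicates, double seed,
                  bool synchronous = false,
                  IntegerVector record_joint_at = IntegerVector(0),
                  int window = 0) {
  const int n = pa.size();
  if (node_off.size() != n + 1) stop("node_off must have length n + 1");
  if (horizon < 1) stop("horizon must be >= 1");
  if (replicates < 1) stop("replicates must be >= 1");
  const uint64_t base = (uint64_t)(int64_t)seed;

  const bool record = record_joint_at.size() > 0;
  if (record && n > 20) stop("joint-state recording requires <= 20 nodes");
  const int n_states = record ? (1 << n) : 0;

  if (window < 0 || window > horizon) stop("window must lie in [0, horizon]");

  NumericMatrix counts(horizon + 1, n);
  NumericMatrix joint(record ? record_joint_at.size() : 0, n_states);
  // per-replicate mean state over the last `window` iterations
  NumericMatrix repw(window > 0 ? replicates : 0, window > 0 ? n : 0);
  std::vector<int> rec_at(record_joint_at.begin(), record_joint_at.end());

  std::vector<int> stack(2 * code.size() / 2 + 4);
  std::vector<int> state(n), newstate(n), perm(n), fvals(n);
  const int *cd = INTEGER(code);
  const int *off = INTEGER(node_off);

  for (int r = 0; r < replicates; ++r) {
    Xoshiro256pp rng(replicate_seed(base, (uint64_t)r));
    for (int i = 0; i < n; ++i) {
      state[i] = (init[i] == -1) ? (rng.unif() < 0.5 ? 1 : 0) : init[i];
    }
    for (int i = 0; i < n; ++i) counts(0, i) += state[i];
    size_t rec_idx = 0;
    if (record) {
      while (rec_idx < rec_at.size() && rec_at[rec_idx] == 0) {
        int s = 0;
        for (int i = 0; i < n; ++i) s = (s << 1) | state[i];
        joint(rec_idx, s) += 1.0;
        ++rec_idx;
      }
    }
    for (int t = 1; t <= horizon; ++t) {
      if (synchronous) {
        for (int i = 0; i < n; ++i)
          fvals[i] = eval_rule(cd, off[i], off[i + 1], state, stack.data());
        for (int i = 0; i < n; ++i)
          newstate[i] = update_bit(fvals[i], state[i], pa[i], pd[i], rng.unif());
        state = newstate;
      } else {
        // fresh random permutation each iteration (Fisher-Yates); later nodes
        // in the permutation see earlier nodes' updated values
        for (int i = 0; i < n; ++i) perm[i] = i;
        for (int i = n - 1; i >= 1; --i) {
          int j = rng.below(i + 1);
          int tmp = perm[i]; perm[i] = perm[j]; perm[j] = tmp;
        }
        for (int k = 0; k < n; ++k) {
          int i = perm[k];
          int f = eval_rule(cd, off[i], off[i + 1], state, stack.data());
          state[i] = update_bit(f, state[i], pa[i], pd[i], rng.unif());
        }
      }
      for (int i = 0; i < n; ++i) counts(t, i) += state[i];
      if (window > 0 && t > horizon - window) {
        for (int i = 0; i < n; ++i) repw(r, i) += state[i];
      }
      if (record) {
        while (rec_idx < rec_at.size() && rec_at[rec_idx] == t) {
          int s = 0;
          for (int i = 0; i < n; ++i) s = (s << 1) | state[i];
          joint(rec_idx, s) += 1.0;
          ++rec_idx;
        }
      }
    }
  }

  for (int t = 0; t <= horizon; ++t)
    for (int i = 0; i < n; ++i) counts(t, i) /= replicates;
  if (record)
    for (int k = 0; k < joint.nrow(); ++k)
      for (int s = 0; s < n_states; ++s) joint(k, s) /= replicates;
  if (window > 0)
    for (int r = 0; r < replicates; ++r)
      for (int i = 0; i < n; ++i) repw(r, i) /= window;

  return List::create(_["activity"] = counts, _["joint"] = joint,
                      _["replicate_steady"] = repw);
}

// Single elementary update draws, for frequency checks of the update rule
// semantics without going through an ensemble.
// [[Rcpp::export(name = ".cpp_update_draws")]]
IntegerVector cpp_update_draws(int f, int x, double pa, double pd,
                               int ndraws, double seed) {
  Xoshiro256pp rng(replicate_seed((uint64_t)(int64_t)seed, 0));
  IntegerVector out(ndraws);
  for (int k = 0; k < ndraws; ++k) out[k] = update_bit(f, x, pa, pd, rng.unif());
  return out;
}
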