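// Structured-coalescent engine for the two-deme split-migration model.
//
// Time runs backward in units of 2*N_ref generations.  For t < T two demes
// of relative sizes nu1, nu2 exchange lineages symmetrically: each lineage
// migrates at rate m/2 and each within-deme pair coalesces at rate 1/nu_k.
// At t = T all lineages drop into a single ancestral deme of relative size 1.
//
// All randomness comes from a self-contained xoshiro256++ generator seeded
// via splitmix64, so streams are reproducible across platforms and can be
// keyed per replicate / per locus (common random numbers for the likelihood
// surface; per-locus streams so the locus count can grow without
// reshuffling earlier loci).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// deterministic stream key for (seed, index) pairs
static inline uint64_t mix2(uint64_t seed, uint64_t idx) {
  uint64_t x = seed ^ (0x9E3779B97F4A7C15ULL * (idx + 1));
  splitmix64(x);
  return splitmix64(x);
}

struct Xoshiro256 {
  uint64_t s[4];
  explicit Xoshiro256(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on [0, 1), 53-bit resolution
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  double rexp(double rate) { return -std::log1p(-unif()) / rate; }
  // integer uniform on {0, ..., n-1}; n is tiny here, modulo bias negligible
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

// small-mean Poisson (Knuth); means here are O(theta * tree length) << 50
static int rpois_small(double lambda, Xoshiro256 &rng) {
  if (lambda <= 0.0) return 0;
  const double limit = std::exp(-lambda);
  int k = 0;
  double p = 1.0;
  do {
    ++k;
    p *= rng.unif();
  } while (p > limit);
  return k - 1;
}

struct Branch {
  uint64_t mask;   // bit b set <=> branch subtends sampled haplotype b
  double len;      // branch length in 2*N_ref generations
};

// Simulate one genealogy of n1 + n2 sampled haplotypes (<= 64 total).
// Finalized branches (all edges except the root stub) are appended to
// `branches`; coalescence times are appended to `times`.
static void sim_tree(int n1, int n2,
                     double nu1, double nu2, double Tsplit, double m,
                     Xoshiro256 &rng,
                     std::vector<Branch> &branches,
                     std::vector<double> &times) {
  const int ntot = n1 + n2;
  std::vector<uint64_t> mask(ntot);
  std::vector<int> deme(ntot);
  std::vector<double> birth(ntot, 0.0);
  for (int b = 0; b < ntot; ++b) {
    mask[b] = 1ULL << b;
    deme[b] = (b < n1) ? 0 : 1;
  }
  int k = ntot;
  double t = 0.0;

  auto merge_pair = [&](int a, int b) {
    branches.push_back({mask[a], t - birth[a]});
    branches.push_back({mask[b], t - birth[b]});
    times.push_back(t);
    mask[a] |= mask[b];
    birth[a] = t;
    // demes are already merged or irrelevant once this is called post-T;
    // pre-T merges only happen within a deme so deme[a] stays valid
    mask[b] = mask[k - 1];
    deme[b] = deme[k - 1];
    birth[b] = birth[k - 1];
    --k;
  };

  // phase 1: two demes, t < Tsplit
  while (k > 1 && t < Tsplit) {
    int k1 = 0;
    for (int i = 0; i < k; ++i) if (deme[i] == 0) ++k1;
    const int k2 = k - k1;
    const double c1 = 0.5 * k1 * (k1 - 1) / nu1;
    const double c2 = 0.5 * k2 * (k2 - 1) / nu2;
    const double mg = 0.5 * m * k;
    const double tot = c1 + c2 + mg;
    if (tot <= 0.0) { t = Tsplit; break; }
    const double dt = rng.rexp(tot);
    if (t + dt >= Tsplit) { t = Tsplit; break; }
    t += dt;
    double u = rng.unif() * tot;
    if (u < c1 + c2) {
      const int d = (u < c1) ? 0 : 1;
      const int kd = (d == 0) ? k1 : k2;
      // pick an unordered pair uniformly within deme d
      int r1 = rng.below(kd);
      int r2 = rng.below(kd - 1);
      if (r2 >= r1) ++r2;
      int a = -1, b = -1, seen = 0;
      for (int i = 0; i < k; ++i) {
        if (deme[i] == d) {
          if (seen == r1) a = i;
          if (seen == r2) b = i;
          ++seen;
        }
      }
      if (a > b) std::swap(a, b);
      merge_pair(a, b);
    } else {
      const int i = rng.below(k);
      deme[i] ^= 1;
    }
  }

  // phase 2: single ancestral deme of relative size 1
  while (k > 1) {
    const double rate = 0.5 * k * (k - 1);
    t += rng.rexp(rate);
    int a = rng.below(k);
    int b = rng.below(k - 1);
    if (b >= a) ++b;
    if (a > b) std::swap(a, b);
    merge_pair(a, b);
  }
}

static inline int popcount_range(uint64_t mask, int lo, int n) {
  const uint64_t window = (n >= 64) ? ~0ULL : (((1ULL << n) - 1) << lo);
  #if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(mask & window);
  #else
  uint64_t v = mask & window; int c = 0;
  while (v) { v &= v - 1; ++c; }
  return c;
  #endif
}

// [[Rcpp::export]]
List sim_genealogy_cpp(int n1, int n2, double nu1, double nu2,
                       double Tsplit, double m, double seed) {
  std::vector<Branch> branches;
  std::vector<double> times;
  Xoshiro256 rng((uint64_t)seed);
  sim_tree(n1, n2, nu1, nu2, Tsplit, m, rng, branches, times);
  const int nb = (int)branches.size();
  NumericMatrix out(nb, 3);
  double total = 0.0;
  for (int i = 0; i < nb; ++i) {
    out(i, 0) = branches[i].len;
    out(i, 1) = popcount_range(branches[i].mask, 0, n1);
    out(i, 2) = popcount_range(branches[i].mask, n1, n2);
    total += branches[i].len;
  }
  colnames(out) = CharacterVector::create("length", "n_pop1", "n_pop2");
  return List::create(_["branches"] = out,
                      _["times"] = NumericVector(times.begin(), times.end()),
                      _["total_length"] = total);
}

// Monte Carlo expected branch lengths by descendant configuration:
// M[i, j] = (1/2) * mean over R genealogies of the total branch length
// subtending exactly i pop1- and j pop2-haplotypes, i.e. the expected
// joint SFS at theta = 1.  Replicate r uses stream key mix2(seed, r), so
// the same seed gives common random numbers across parameter values.
//
// Hot path for the likelihood surface: descendant counts are tracked
// incrementally (no masks) and branch lengths accumulate straight into M.
// [[Rcpp::export]]
NumericMatrix branch_sfs_cpp(int n1, int n2, double nu1, double nu2,
                             double Tsplit, double m, int R, double seed) {
  NumericMatrix M(n1 + 1, n2 + 1);
  double *Md = REAL(M);
  const int ncol1 = n1 + 1;
  const int ntot = n1 + n2;
  std::vector<int> ci(ntot), cj(ntot), deme(ntot);
  std::vector<double> birth(ntot);
  for (int r = 0; r < R; ++r) {
    Xoshiro256 rng(mix2((uint64_t)seed, (uint64_t)r));
    int k = ntot, k1 = n1;
    for (int b = 0; b < ntot; ++b) {
      ci[b] = (b < n1) ? 1 : 0;
      cj[b] = (b < n1) ? 0 : 1;
      deme[b] = (b < n1) ? 0 : 1;
      birth[b] = 0.0;
    }
    double t = 0.0;
    bool twoDemes = Tsplit > 0.0;
    while (k > 1) {
      double dt;
      int a = -1, b2 = -1;
      if (twoDemes) {
        const int k2 = k - k1;
        const double c1 = 0.5 * k1 * (k1 - 1) / nu1;
        const double c2 = 0.5 * k2 * (k2 - 1) / nu2;
        const double mg = 0.5 * m * k;
        const double tot = c1 + c2 + mg;
        dt = (tot > 0.0) ? rng.rexp(tot) : (Tsplit - t + 1.0);
        if (t + dt >= Tsplit) { t = Tsplit; twoDemes = false; continue; }
        t += dt;
        double u = rng.unif() * tot;
        if (u < c1 + c2) {
          const int d = (u < c1) ? 0 : 1;
          const int kd = (d == 0) ? k1 : k2;
          int r1 = rng.below(kd);
          int r2 = rng.below(kd - 1);
          if (r2 >= r1) ++r2;
          int seen = 0;
          for (int i = 0; i < k; ++i) {
            if (deme[i] == d) {
              if (seen == r1) a = i;
              if (seen == r2) b2 = i;
              ++seen;
            }
          }
        } else {
          const int i = rng.below(k);
          if (deme[i] == 0) { deme[i] = 1; --k1; }
          else { deme[i] = 0; ++k1; }
          continue;
        }
      } else {
        t += rng.rexp(0.5 * k * (k - 1));
        a = rng.below(k);
        b2 = rng.below(k - 1);
        if (b2 >= a) ++b2;
      }
      if (a > b2) std::swap(a, b2);
      // finalize the two child branches, merge into slot a
      Md[ci[a] + ncol1 * cj[a]] += t - birth[a];
      Md[ci[b2] + ncol1 * cj[b2]] += t - birth[b2];
      ci[a] += ci[b2];
      cj[a] += cj[b2];
      birth[a] = t;
      if (twoDemes && deme[b2] == 0) --k1;
      ci[b2] = ci[k - 1];
      cj[b2] = cj[k - 1];
      deme[b2] = deme[k - 1];
      birth[b2] = birth[k - 1];
      --k;
    }
  }
  const double scale = 0.5 / (double)R;
  for (int c = 0; c < ncol1 * (n2 + 1); ++c) Md[c] *= scale;
  return M;
}

// One-SNP-per-locus dataset simulation.  Per locus: simulate a genealogy
// (stream key mix2(seed, locus)), drop Poisson(theta_locus/2 * total
// length) mutations, keep the locus if at least one lands, and pick the
// defining SNP uniformly among its mutations (equivalently: a branch with
// probability proportional to length).  Returns the 0/1 haplotype matrix
// of retained loci plus bookkeeping.
// [[Rcpp::export]]
List sim_loci_cpp(int n1, int n2, double nu1, double nu2,
                  double Tsplit, double m, double theta_locus,
                  int L, double seed) {
  const int ntot = n1 + n2;
  std::vector<Branch> branches;
  std::vector<double> times;
  std::vector<uint64_t> snp_masks;
  std::vector<int> kept;
  IntegerVector n_mut(L);
  NumericVector pi_tree(L);  // E[pairwise diversity | genealogy]
  const double pair_norm = 2.0 / ((double)ntot * (ntot - 1));
  snp_masks.reserve(L);
  for (int l = 0; l < L; ++l) {
    branches.clear();
    times.clear();
    Xoshiro256 rng(mix2((uint64_t)seed, (uint64_t)l));
    sim_tree(n1, n2, nu1, nu2, Tsplit, m, rng, branches, times);
    double total = 0.0, pisum = 0.0;
    for (size_t b = 0; b < branches.size(); ++b) {
      total += branches[b].len;
      const int i = popcount_range(branches[b].mask, 0, ntot);
      pisum += branches[b].len * i * (ntot - i);
    }
    pi_tree[l] = 0.5 * theta_locus * pisum * pair_norm;
    const int nmut = rpois_small(0.5 * theta_locus * total, rng);
    n_mut[l] = nmut;
    if (nmut == 0) continue;
    // choose one mutation uniformly: branch weight = branch length
    double u = rng.unif() * total;
    uint64_t chosen = branches.back().mask;
    for (size_t b = 0; b < branches.size(); ++b) {
      u -= branches[b].len;
      if (u <= 0.0) { chosen = branches[b].mask; break; }
    }
    snp_masks.push_back(chosen);
    kept.push_back(l + 1);
  }
  const int nvar = (int)snp_masks.size();
  IntegerMatrix alleles(nvar, ntot);
  for (int r = 0; r < nvar; ++r)
    for (int c = 0; c < ntot; ++c)
      alleles(r, c) = (int)((snp_masks[r] >> c) & 1ULL);
  return List::create(_["alleles"] = alleles,
                      _["kept_locus"] = IntegerVector(kept.begin(), kept.end()),
                      _["n_attempted"] = L,
                      _["n_mut"] = n_mut,
                      _["pi_tree"] = pi_tree);
}
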