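// Permutation kernels for the reverse-genetics tally statistics.
//
// The statistics operate on minor-allele homozygotes (HZMA): for each
// (re)assignment of genotypes to subjects the set of qualifying
// constituent diagnoses is re-derived from the newly assigned HZMA set
// (>= minCount carriers; model 2 additionally requires a one-sided Fisher
// excess vs common-allele homozygotes at the configured threshold), and
// the tally counts HZMA subjects carrying any qualifying diagnosis.  The
// re-derivation inside every permutation is what makes the naive p-value
// anti-conservative and forces this permutation null, so it has to be fast:
// the type-I simulations run ~5e7 assignments.
//
// RNG: self-contained splitmix64-seeded xoshiro256++ so that streams are
// (a) reproducible across platforms and (b) independent per SNP/draw,
// making results invariant to execution order.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Rng {
  uint64_t s[4];
  Rng(double seed, double stream) {
    uint64_t x = (uint64_t)(int64_t)seed;
    x ^= (uint64_t)(int64_t)stream * 0x9E3779B97F4A7C15ULL;
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
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // Lemire bounded draw in [0, n)
  inline uint32_t bounded(uint32_t n) {
    uint64_t m = (uint64_t)(uint32_t)next() * n;
    uint32_t l = (uint32_t)m;
    if (l < n) {
      uint32_t t = (uint32_t)(-(int32_t)n) % n;
      while (l < t) {
        m = (uint64_t)(uint32_t)next() * n;
        l = (uint32_t)m;
      }
    }
    return (uint32_t)(m >> 32);
  }
};

// Subject diagnosis masks: W 64-bit words per subject, bit g set iff the
// subject carries constituent group g.
struct Masks {
  int n, G, W;
  std::vector<uint64_t> bits;    // n * W
  std::vector<int> K;            // carriers per group over all subjects
  Masks(const IntegerMatrix& dx) {
    n = dx.nrow();
    G = dx.ncol();
    W = (G + 63) / 64;
    bits.assign((size_t)n * W, 0ULL);
    K.assign(G, 0);
    for (int g = 0; g < G; ++g) {
      int w = g >> 6, b = g & 63;
      for (int i = 0; i < n; ++i) {
        if (dx(i, g) != 0) {
          bits[(size_t)i * W + w] |= (1ULL << b);
          K[g]++;
        }
      }
    }
  }
  inline const uint64_t* row(int i) const { return &bits[(size_t)i * W]; }
};

// Scratch for one tally evaluation.
struct Scratch {
  std::vector<int> cnt;        // per-group HZMA carrier count
  std::vector<int> cxc;        // per-group excluded-class carrier count
  std::vector<int> touched;    // groups with cnt > 0
  std::vector<uint64_t> rg1m, rg2m, candm;
  Scratch(int G, int W)
      : cnt(G, 0), cxc(G, 0), rg1m(W, 0ULL), rg2m(W, 0ULL), candm(W, 0ULL) {
    touched.reserve(G);
  }
};

// Count HZMA carriers per group for subjects idx[0..h); fills sc.cnt and
// sc.touched (sc.cnt must be all-zero on entry, restored before return by
// caller via resetCounts).
inline void countGroups(const Masks& M, const int* idx, int h, Scratch& sc) {
  sc.touched.clear();
  for (int i = 0; i < h; ++i) {
    const uint64_t* m = M.row(idx[i]);
    for (int w = 0; w < M.W; ++w) {
      uint64_t mm = m[w];
      while (mm) {
        int g = (w << 6) + __builtin_ctzll(mm);
        if (sc.cnt[g]++ == 0) sc.touched.push_back(g);
        mm &= mm - 1;
      }
    }
  }
}

inline void resetCounts(Scratch& sc) {
  for (int g : sc.touched) sc.cnt[g] = 0;
}

inline int tallyMask(const Masks& M, const int* idx, int h,
                     const std::vector<uint64_t>& mask) {
  int t = 0;
  for (int i = 0; i < h; ++i) {
    const uint64_t* m = M.row(idx[i]);
    for (int w = 0; w < M.W; ++w) {
      if (m[w] & mask[w]) { ++t; break; }
    }
  }
  return t;
}

inline int tallyAny(const Masks& M, const int* idx, int h) {
  int t = 0;
  for (int i = 0; i < h; ++i) {
    const uint64_t* m = M.row(idx[i]);
    for (int w = 0; w < M.W; ++w) {
      if (m[w]) { ++t; break; }
    }
  }
  return t;
}

// Evaluate the three tallies (rg1, rg2, recessive-permutation) for the
// assignment with HZMA = idx[0..h) and excluded class (heterozygote or
// missing) = exc[0..nExc).  bmax[a] is the largest common-homozygote
// carrier count b for which the one-sided Fisher p at HZMA count a stays
// below the threshold (-1: none); K[g] - a - c gives b.
inline void evalTallies(const Masks& M, const int* idx, int h,
                        const int* exc, int nExc, int minCount,
                        const int* bmax, Scratch& sc,
                        int& t1, int& t2, int& trec) {
  countGroups(M, idx, h, sc);
  std::fill(sc.rg1m.begin(), sc.rg1m.end(), 0ULL);
  std::fill(sc.rg2m.begin(), sc.rg2m.end(), 0ULL);
  int nCand = 0;
  for (int g : sc.touched) {
    if (sc.cnt[g] >= minCount) {
      sc.rg1m[g >> 6] |= (1ULL << (g & 63));
      ++nCand;
    }
  }
  t1 = t2 = 0;
  if (nCand > 0) {
    t1 = tallyMask(M, idx, h, sc.rg1m);
    // model 2: Fisher filter needs carriers among common homozygotes
    if (nExc > 0) {
      for (int g : sc.touched) sc.cxc[g] = 0;
      for (int j = 0; j < nExc; ++j) {
        const uint64_t* m = M.row(exc[j]);
        for (int w = 0; w < M.W; ++w) {
          uint64_t mm = m[w] & sc.rg1m[w];
          while (mm) {
            int g = (w << 6) + __builtin_ctzll(mm);
            sc.cxc[g]++;
            mm &= mm - 1;
          }
        }
      }
    }
    for (int g : sc.touched) {
      int a = sc.cnt[g];
      if (a < minCount) continue;
      int b = M.K[g] - a - (nExc > 0 ? sc.cxc[g] : 0);
      if (b <= bmax[a]) sc.rg2m[g >> 6] |= (1ULL << (g & 63));
      if (nExc > 0) sc.cxc[g] = 0;
    }
    bool any2 = false;
    for (int w = 0; w < M.W; ++w) if (sc.rg2m[w]) { any2 = true; break; }
    if (any2) t2 = tallyMask(M, idx, h, sc.rg2m);
  }
  trec = tallyAny(M, idx, h);
  resetCounts(sc);
}

}  // namespace

// Observed tallies for an explicit homozygote split (0-based index vectors).
// [[Rcpp::export]]
IntegerVector cpp_observed_tallies(IntegerMatrix dx, IntegerVector hzmaIdx,
                                   IntegerVector excIdx, int minCount,
                                   IntegerVector bmax) {
  Masks M(dx);
  Scratch sc(M.G, M.W);
  std::vector<int> idx(hzmaIdx.begin(), hzmaIdx.end());
  std::vector<int> exc(excIdx.begin(), excIdx.end());
  int t1, t2, trec;
  evalTallies(M, idx.data(), (int)idx.size(), exc.data(), (int)exc.size(),
              minCount, bmax.begin(), sc, t1, t2, trec);
  return IntegerVector::create(_["rg1"] = t1, _["rg2"] = t2, _["rec"] = trec);
}

// Stratified permutation null for one SNP.  geno: 0/1/2, NA for missing;
// strata: 1-based stratum labels.  Genotype labels are reassigned among
// subjects within each stratum, preserving per-stratum genotype counts.
// Returns observed tallies, counts of permutations with tally >= observed,
// and (optionally) the full B x 3 tally matrix.
// [[Rcpp::export]]
List cpp_strat_perm(IntegerMatrix dx, IntegerVector geno, IntegerVector strata,
                    int B, int minCount, IntegerVector bmax, double seed,
                    double stream, bool returnTallies = false) {
  Masks M(dx);
  int n = M.n;
  if (geno.size() != n || strata.size() != n)
    stop("geno/strata length must match diagnosis matrix rows");
  Scratch sc(M.G, M.W);

  // observed split
  std::vector<int> obsH, obsE;
  for (int i = 0; i < n; ++i) {
    int g = geno[i];
    if (g == NA_INTEGER) { obsE.push_back(i); continue; }
    if (g == 2) obsH.push_back(i);
    else if (g == 1) obsE.push_back(i);
  }
  int t1o, t2o, treco;
  evalTallies(M, obsH.data(), (int)obsH.size(), obsE.data(), (int)obsE.size(),
              minCount, bmax.begin(), sc, t1o, t2o, treco);

  // per-stratum subject lists and label counts
  int S = 0;
  for (int i = 0; i < n; ++i) S = std::max(S, (int)strata[i]);
  std::vector<std::vector<int>> sub(S);
  std::vector<int> k2(S, 0), kx(S, 0);
  for (int i = 0; i < n; ++i) {
    int s = strata[i] - 1;
    sub[s].push_back(i);
    int g = geno[i];
    if (g == NA_INTEGER || g == 1) kx[s]++;
    else if (g == 2) k2[s]++;
  }

  Rng rng(seed, stream);
  std::vector<int> hz, exc;
  hz.reserve(obsH.size());
  exc.reserve(obsE.size());
  IntegerMatrix tallies(returnTallies ? B : 0, 3);
  int ge1 = 0, ge2 = 0, gerec = 0;
  for (int b = 0; b < B; ++b) {
    hz.clear(); exc.clear();
    for (int s = 0; s < S; ++s) {
      std::vector<int>& v = sub[s];
      int ns = (int)v.size();
      int need = k2[s] + kx[s];
      for (int i = 0; i < need; ++i) {
        int j = i + (int)rng.bounded((uint32_t)(ns - i));
        std::swap(v[i], v[j]);
        if (i < k2[s]) hz.push_back(v[i]); else exc.push_back(v[i]);
      }
    }
    int t1, t2, trec;
    evalTallies(M, hz.data(), (int)hz.size(), exc.data(), (int)exc.size(),
                minCount, bmax.begin(), sc, t1, t2, trec);
    if (t1 >= t1o) ++ge1;
    if (t2 >= t2o) ++ge2;
    if (trec >= treco) ++gerec;
    if (returnTallies) { tallies(b, 0) = t1; tallies(b, 1) = t2; tallies(b, 2) = trec; }
  }
  return List::create(
      _["t_obs"] = IntegerVector::create(_["rg1"] = t1o, _["rg2"] = t2o, _["rec"] = treco),
      _["count_ge"] = IntegerVector::create(_["rg1"] = ge1, _["rg2"] = ge2, _["rec"] = gerec),
      _["n_hzma"] = (int)obsH.size(),
      _["tallies"] = tallies);
}

// Single-stratum sampling null used by the ROC simulations: the observed
// HZMA set is hzmaIdx (0-based); every permutation redraws |hzma| subjects
// from the whole cohort, the remainder acting as common homozygotes.
// [[Rcpp::export]]
List cpp_sample_perm(IntegerMatrix dx, IntegerVector hzmaIdx, int B,
                     int minCount, IntegerVector bmax, double seed,
                     double stream) {
  Masks M(dx);
  int n = M.n;
  int h = hzmaIdx.size();
  if (h < 1 || h > n) stop("invalid HZMA size");
  Scratch sc(M.G, M.W);
  std::vector<int> obsH(hzmaIdx.begin(), hzmaIdx.end());
  int t1o, t2o, treco;
  evalTallies(M, obsH.data(), h, nullptr, 0, minCount, bmax.begin(), sc,
              t1o, t2o, treco);
  Rng rng(seed, stream);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  int ge1 = 0, ge2 = 0, gerec = 0;
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < h; ++i) {
      int j = i + (int)rng.bounded((uint32_t)(n - i));
      std::swap(idx[i], idx[j]);
    }
    int t1, t2, trec;
    evalTallies(M, idx.data(), h, nullptr, 0, minCount, bmax.begin(), sc,
                t1, t2, trec);
    if (t1 >= t1o) ++ge1;
    if (t2 >= t2o) ++ge2;
    if (trec >= treco) ++gerec;
  }
  return List::create(
      _["t_obs"] = IntegerVector::create(_["rg1"] = t1o, _["rg2"] = t2o, _["rec"] = treco),
      _["count_ge"] = IntegerVector::create(_["rg1"] = ge1, _["rg2"] = ge2, _["rec"] = gerec),
      _["B"] = B);
}

// Type-I error simulation: for each of nSnps randomized SNPs with genotype
// counts (n2 = HZMA, n1 = heterozygote), draw the observed assignment
// uniformly (a global genotype-label shuffle), then B permutation
// reassignments; report the plain permutation p = #(T_perm >= T_obs)/B for
// models rg1 and rg2.  bmaxMat row j gives the model-2 Fisher cutoffs for
// SNP j indexed by HZMA carrier count a (column a).
// [[Rcpp::export]]
NumericMatrix cpp_type1_sim(IntegerMatrix dx, IntegerVector n2v,
                            IntegerVector n1v, IntegerMatrix bmaxMat, int B,
                            int minCount, double seed) {
  Masks M(dx);
  int n = M.n;
  int nSnps = n2v.size();
  if (n1v.size() != nSnps || bmaxMat.nrow() != nSnps)
    stop("n2, n1 and bmax row counts must agree");
  Scratch sc(M.G, M.W);
  NumericMatrix out(nSnps, 4);
  colnames(out) = CharacterVector::create("t1_obs", "t2_obs", "p_rg1", "p_rg2");
  std::vector<int> idx(n);
  std::vector<int> bmax(bmaxMat.ncol());
  for (int snp = 0; snp < nSnps; ++snp) {
    int h = n2v[snp], nhet = n1v[snp];
    if (h < 1 || h + nhet > n) stop("invalid genotype counts");
    for (int a = 0; a < (int)bmax.size(); ++a) bmax[a] = bmaxMat(snp, a);
    Rng rng(seed, (double)(snp + 1));
    for (int i = 0; i < n; ++i) idx[i] = i;
    int t1o = 0, t2o = 0, ge1 = 0, ge2 = 0;
    for (int b = 0; b <= B; ++b) {   // b = 0 is the observed assignment
      for (int i = 0; i < h; ++i) {
        int j = i + (int)rng.bounded((uint32_t)(n - i));
        std::swap(idx[i], idx[j]);
      }
      // heterozygote positions are needed only when a candidate group exists
      countGroups(M, idx.data(), h, sc);
      std::fill(sc.rg1m.begin(), sc.rg1m.end(), 0ULL);
      std::fill(sc.rg2m.begin(), sc.rg2m.end(), 0ULL);
      int nCand = 0;
      for (int g : sc.touched) {
        if (sc.cnt[g] >= minCount) {
          sc.rg1m[g >> 6] |= (1ULL << (g & 63));
          ++nCand;
        }
      }
      int t1 = 0, t2 = 0;
      if (nCand > 0) {
        t1 = tallyMask(M, idx.data(), h, sc.rg1m);
        if (nhet > 0) {
          for (int i = h; i < h + nhet; ++i) {
            int j = i + (int)rng.bounded((uint32_t)(n - i));
            std::swap(idx[i], idx[j]);
          }
          for (int g : sc.touched) sc.cxc[g] = 0;
          for (int i = h; i < h + nhet; ++i) {
            const uint64_t* m = M.row(idx[i]);
            for (int w = 0; w < M.W; ++w) {
              uint64_t mm = m[w] & sc.rg1m[w];
              while (mm) {
                int g = (w << 6) + __builtin_ctzll(mm);
                sc.cxc[g]++;
                mm &= mm - 1;
              }
            }
          }
        }
        for (int g : sc.touched) {
          int a = sc.cnt[g];
          if (a < minCount) continue;
          int bcar = M.K[g] - a - (nhet > 0 ? sc.cxc[g] : 0);
          if (bcar <= bmax[a]) sc.rg2m[g >> 6] |= (1ULL << (g & 63));
          if (nhet > 0) sc.cxc[g] = 0;
        }
        bool any2 = false;
        for (int w = 0; w < M.W; ++w) if (sc.rg2m[w]) { any2 = true; break; }
        if (any2) t2 = tallyMask(M, idx.data(), h, sc.rg2m);
      }
      resetCounts(sc);
      if (b == 0) { t1o = t1; t2o = t2; }
      else {
        if (t1 >= t1o) ++ge1;
        if (t2 >= t2o) ++ge2;
      }
    }
    out(snp, 0) = t1o;
    out(snp, 1) = t2o;
    out(snp, 2) = (double)ge1 / B;
    out(snp, 3) = (double)ge2 / B;
    if ((snp & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
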