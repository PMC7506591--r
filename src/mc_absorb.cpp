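// Monte-Carlo absorption oracle for the seeded random walker.
// Simulates weighted random walks on an undirected graph (CSR adjacency)
// until a seed node is hit; returns per-start-node absorption counts per
// label. Own xorshift RNG so results are bit-reproducible across platforms.

#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t xorshift64(uint64_t &s) {
  s ^= s << 13;
  s ^= s >> 7;
  s ^= s << 17;
  return s;
}

static inline double runif01(uint64_t &s) {
  return (xorshift64(s) >> 11) * (1.0 / 9007199254740992.0);  // 2^53
}

// [[Rcpp::export]]
IntegerMatrix mc_absorb_cpp(IntegerVector ptr, IntegerVector nbr,
                            NumericVector wt, IntegerVector seed_label,
                            int n_labels, int n_walks, int rng_seed) {
  const int n = seed_label.size();
  IntegerMatrix counts(n, n_labels);

  // per-node cumulative neighbour weights for O(deg) inverse-CDF sampling
  std::vector<double> cumw(wt.size());
  std::vector<double> totw(n);
  for (int v = 0; v < n; ++v) {
    double acc = 0.0;
    for (int k = ptr[v]; k < ptr[v + 1]; ++k) {
      acc += wt[k];
      cumw[k] = acc;
    }
    totw[v] = acc;
  }

  uint64_t state = 0x9E3779B97F4A7C15ULL ^ (uint64_t)(rng_seed * 2654435761u);
  if (state == 0) state = 0x9E3779B97F4A7C15ULL;
  for (int i = 0; i < 64; ++i) xorshift64(state);

  for (int start = 0; start < n; ++start) {
    if (seed_label[start] > 0) continue;   // seeds are boundary, not sampled
    for (int w = 0; w < n_walks; ++w) {
      int v = start;
      while (seed_label[v] == 0) {
        double u = runif01(state) * totw[v];
        int lo = ptr[v], hi = ptr[v + 1];
        // linear scan: degree <= 4 on the lattice
        int k = lo;
        while (k < hi - 1 && cumw[k] < u) ++k;
        v = nbr[k];
      }
      counts(start, seed_label[v] - 1) += 1;
    }
    Rcpp::checkUserInterrupt();
  }
  return counts;
}
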