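#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// Monte-Carlo gene dropping: founders carry two unique allele labels; each
// meiosis transmits one of the parent's two alleles at random. The kinship
// of (i, j) is estimated as the mean over drops of the IBD probability of
// one allele drawn at random from each, i.e. (1/4) * #matching ordered
// allele pairs. A single drop serves every requested pair, and the self
// pair (i, i) yields (1 + F_i)/2 as it should.

// father/mother: 0-based indices, -1 for founders; individuals must be in
// topological order (parents before children). pairs: 2-column 0-based.
// [[Rcpp::export]]
List cpp_mc_kinship(IntegerVector father, IntegerVector mother,
                    IntegerMatrix pairs, int ndrops, double seed) {
  const int n = father.size(), np = pairs.nrow();
  std::vector<int> a1(n), a2(n);
  std::vector<double> sum(np, 0.0), sumsq(np, 0.0);
  SplitMix64 rng(mix_seed((uint64_t)seed, 0x67656e65ULL));

  for (int d = 0; d < ndrops; ++d) {
    int lab = 0;
    for (int i = 0; i < n; ++i) {
      const int f = father[i], m = mother[i];
      if (f < 0) { a1[i] = lab++; a2[i] = lab++; }
      else {
        a1[i] = (rng.next() & 1) ? a1[f] : a2[f];
        a2[i] = (rng.next() & 1) ? a1[m] : a2[m];
      }
    }
    for (int q = 0; q < np; ++q) {
      const int i = pairs(q, 0), j = pairs(q, 1);
      const int match = (a1[i] == a1[j]) + (a1[i] == a2[j]) +
                        (a2[i] == a1[j]) + (a2[i] == a2[j]);
      const double k = 0.25 * match;
      sum[q] += k;
      sumsq[q] += k * k;
    }
  }

  NumericVector est(np), se(np);
  for (int q = 0; q < np; ++q) {
    const double mu = sum[q] / ndrops;
    const double var = sumsq[q] / ndrops - mu * mu;
    est[q] = mu;
    se[q] = std::sqrt(var > 0 ? var / ndrops : 0.0);
  }
  return List::create(_["estimate"] = est, _["se"] = se);
}
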