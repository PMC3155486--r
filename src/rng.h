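#ifndef KINFOREST_RNG_H
#define KINFOREST_RNG_H

#include <cstdint>

// splitmix64: small, fast, reproducible across platforms/compilers.
// Each tree gets its own stream derived from (master seed, tree index),
// so results do not depend on evaluation order or thread count.
struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n); Lemire multiply-shift (bias < 2^-32 for small n)
  int bounded(int n) {
    return (int)((((unsigned __int128)next()) * (uint64_t)n) >> 64);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

inline uint64_t mix_seed(uint64_t master, uint64_t stream) {
  SplitMix64 g(master * 0x9e3779b97f4a7c15ULL + stream + 1ULL);
  g.next();
  return g.next();
}

#endif
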