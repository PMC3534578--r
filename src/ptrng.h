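#ifndef PAUSETRACE_PTRNG_H
#define PAUSETRACE_PTRNG_H

#include <cstdint>
#include <cmath>

// xoshiro256++ seeded through splitmix64, with explicit inversion /
// rejection samplers, so that a given integer seed yields the same
// trajectory on every platform and standard library.
class PtRng {
  uint64_t s[4];

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

public:
  explicit PtRng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }

  uint64_t nextU64() {
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

  // uniform on (0, 1]; never 0, so log() below is safe
  double unif() {
    return ((nextU64() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }

  double rexp(double rate) { return -std::log(unif()) / rate; }

  double rnormStd() {
    // Marsaglia polar method; the spare deviate is discarded to keep the
    // consumption of the underlying stream easy to reason about
    double u, v, s2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    return u * std::sqrt(-2.0 * std::log(s2) / s2);
  }

  double rnorm(double mean, double sd) { return mean + sd * rnormStd(); }

  // normal truncated at zero by rejection resampling (no atom at 0)
  double rnormPos(double mean, double sd) {
    double x;
    do {
      x = rnorm(mean, sd);
    } while (x < 0.0);
    return x;
  }
};

// Release-delay distribution attached to a delayed reaction product.
// kind: 0 = point mass (p1 = value), 1 = exponential (p1 = mean),
//       2 = normal truncated at zero (p1 = mean, p2 = sd)
struct Delay {
  int kind;
  double p1, p2;
};

inline double drawDelayC(const Delay &d, PtRng &rng) {
  switch (d.kind) {
  case 0:
    return d.p1;
  case 1:
    return rng.rexp(1.0 / d.p1);
  default:
    return rng.rnormPos(d.p1, d.p2);
  }
}

#endif
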