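#pragma once
#include <cstdint>
#include <cmath>

// xoshiro256++ with splitmix64 seeding; self-contained so that long MC/MD
// loops stay deterministic per seed without touching R's RNG state.
struct RNG {
  uint64_t s[4];
  bool have_normal;
  double cached;

  explicit RNG(uint64_t seed) : have_normal(false), cached(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }

  // uniform in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }

  // uniform integer in {0, ..., n-1}, n >= 1
  int unif_int(int n) {
    int k = (int)(unif() * n);
    return k >= n ? n - 1 : k;
  }

  // standard normal, Box-Muller with caching
  double norm() {
    if (have_normal) { have_normal = false; return cached; }
    double u1, u2;
    do { u1 = unif(); } while (u1 <= 0.0);
    u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925287 * u2;
    cached = r * std::sin(th);
    have_normal = true;
    return r * std::cos(th);
  }
};
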