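#ifndef GANTRYCAM_RNG_H
#define GANTRYCAM_RNG_H

#include <cstdint>
#include <cmath>

// Small, portable, deterministic RNG (splitmix64-seeded xoshiro256++).
// The renderer must produce bit-identical footage for a fixed seed on any
// platform, so we do not rely on implementation-defined std:: distributions.

namespace gcrng {

inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

class Xoshiro256pp {
 public:
  Xoshiro256pp(uint64_t seed, uint64_t stream) {
    uint64_t sm = seed ^ (0x9e3779b97f4a7c15ULL * (stream + 1));
    for (int i = 0; i < 4; ++i) s_[i] = splitmix64(sm);
    has_spare_ = false;
    spare_ = 0.0;
  }

  uint64_t next() {
    const uint64_t result = rotl(s_[0] + s_[3], 23) + s_[0];
    const uint64_t t = s_[1] << 17;
    s_[2] ^= s_[0];
    s_[3] ^= s_[1];
    s_[1] ^= s_[2];
    s_[0] ^= s_[3];
    s_[2] ^= t;
    s_[3] = rotl(s_[3], 45);
    return result;
  }

  // uniform in [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }

  // standard normal, Box-Muller with cached spare
  double norm() {
    if (has_spare_) {
      has_spare_ = false;
      return spare_;
    }
    double u1 = unif(), u2 = unif();
    while (u1 <= 0.0) u1 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare_ = r * std::sin(a);
    has_spare_ = true;
    return r * std::cos(a);
  }

 private:
  static uint64_t rotl(const uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t s_[4];
  bool has_spare_;
  double spare_;
};

}  // namespace gcrng

#endif
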