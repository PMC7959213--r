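#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Deterministic RNG independent of R's global stream: splitmix64-seeded
// xoshiro256++ with Box-Muller normals.  Used only for bulk EEG noise, where
// base-R rnorm is too slow for session-scale simulation; all seeds are
// explicit function arguments.

static inline uint64_t splitmix64_next(uint64_t &x) {
  uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64_next(seed);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1); never exactly 0 so log() below is safe
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Gaussian noise + instantaneous spatial mixing of a 1-D source signal.
// source is pre-padded in front by max(shifts) samples; out[t, c] =
// mix[c] * source[t + maxshift - shifts[c]] + noise_sd * N(0, 1).
// [[Rcpp::export]]
NumericMatrix cpp_mix_noise(NumericVector source, NumericVector mix,
                            IntegerVector shifts, int n_out, double noise_sd,
                            double seed) {
  const int C = mix.size();
  int maxshift = 0;
  for (int c = 0; c < C; ++c) if (shifts[c] > maxshift) maxshift = shifts[c];
  if (source.size() < n_out + maxshift)
    stop("source too short for requested shifts");
  NumericMatrix out(n_out, C);
  Xoshiro256pp rng(static_cast<uint64_t>(seed));
  // Marsaglia polar method (no trig) with a cached spare
  bool have_spare = false;
  double spare = 0.0;
  for (int c = 0; c < C; ++c) {
    const int off = maxshift - shifts[c];
    const double m = mix[c];
    double *col = &out(0, c);
    const double *src = &source[0] + off;
    for (int t = 0; t < n_out; ++t) {
      double z;
      if (have_spare) {
        z = spare;
        have_spare = false;
      } else {
        double u, v, s;
        do {
          u = 2.0 * rng.unif() - 1.0;
          v = 2.0 * rng.unif() - 1.0;
          s = u * u + v * v;
        } while (s >= 1.0 || s == 0.0);
        const double f = std::sqrt(-2.0 * std::log(s) / s);
        z = u * f;
        spare = v * f;
        have_spare = true;
      }
      col[t] = m * src[t] + noise_sd * z;
    }
  }
  return out;
}

// Cascade of second-order sections (direct form II transposed), causal,
// zero initial state, applied independently to each column.
// sos: L x 6 matrix, rows (b0, b1, b2, 1, a1, a2).
// [[Rcpp::export]]
NumericMatrix cpp_sosfilt(NumericMatrix x, NumericMatrix sos) {
  const int n = x.nrow(), C = x.ncol(), L = sos.nrow();
  if (sos.ncol() != 6) stop("sos must have 6 columns");
  NumericMatrix out(n, C);
  // channels are processed 4 at a time so the per-sample recurrences of
  // independent channels interleave (the single-channel dependency chain
  // otherwise dominates on a scalar CPU)
  for (int c0 = 0; c0 < C; c0 += 4) {
    const int nb = std::min(4, C - c0);
    double *col[4];
    for (int j = 0; j < nb; ++j) {
      col[j] = &out(0, c0 + j);
      const double *src = &x(0, c0 + j);
      for (int t = 0; t < n; ++t) col[j][t] = src[t];
    }
    for (int s = 0; s < L; ++s) {
      const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
      const double a1 = sos(s, 4), a2 = sos(s, 5);
      if (nb == 4) {
        double w10 = 0, w20 = 0, w11 = 0, w21 = 0,
               w12 = 0, w22 = 0, w13 = 0, w23 = 0;
        double *y0 = col[0], *y1 = col[1], *y2 = col[2], *y3 = col[3];
        for (int t = 0; t < n; ++t) {
          const double x0 = y0[t], x1 = y1[t], x2 = y2[t], x3 = y3[t];
          const double o0 = b0 * x0 + w10, o1 = b0 * x1 + w11;
          const double o2 = b0 * x2 + w12, o3 = b0 * x3 + w13;
          w10 = b1 * x0 - a1 * o0 + w20; w20 = b2 * x0 - a2 * o0;
          w11 = b1 * x1 - a1 * o1 + w21; w21 = b2 * x1 - a2 * o1;
          w12 = b1 * x2 - a1 * o2 + w22; w22 = b2 * x2 - a2 * o2;
          w13 = b1 * x3 - a1 * o3 + w23; w23 = b2 * x3 - a2 * o3;
          y0[t] = o0; y1[t] = o1; y2[t] = o2; y3[t] = o3;
        }
      } else {
        for (int j = 0; j < nb; ++j) {
          double w1 = 0.0, w2 = 0.0;
          double *y = col[j];
          for (int t = 0; t < n; ++t) {
            const double xn = y[t];
            const double yn = b0 * xn + w1;
            w1 = b1 * xn - a1 * yn + w2;
            w2 = b2 * xn - a2 * yn;
            y[t] = yn;
          }
        }
      }
    }
  }
  return out;
}
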