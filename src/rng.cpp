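#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// splitmix64 finalizer: full-avalanche 64-bit mixing.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

//' Counter-based uniform random numbers
//'
//' Stateless generator mapping (seed, stream id, counter) to a uniform
//' deviate in the open interval (0, 1). Used for all randomness in the
//' package so that draws are reproducible across platforms, independent of
//' R's global RNG, and stable per patient when the cohort grows.
//'
//' @param seed master seed (integer-valued scalar).
//' @param id stream identifiers (e.g. patient ids); recycled against counter.
//' @param counter draw counters within a stream; recycled against id.
//' @return numeric vector of uniforms strictly inside (0, 1).
//' @keywords internal
// [[Rcpp::export]]
NumericVector counter_uniforms(double seed, NumericVector id, NumericVector counter) {
  R_xlen_t ni = id.size(), nc = counter.size();
  R_xlen_t n = std::max(ni, nc);
  if (ni == 0 || nc == 0) return NumericVector(0);
  NumericVector out(n);
  uint64_t s = mix64((uint64_t)(int64_t)seed);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t a = (uint64_t)(int64_t)id[ni == 1 ? 0 : i % ni];
    uint64_t b = (uint64_t)(int64_t)counter[nc == 1 ? 0 : i % nc];
    uint64_t z = mix64(mix64(s ^ a) ^ (b + 0x243F6A8885A308D3ULL));
    // 53-bit mantissa, offset by half an ulp: never exactly 0 or 1
    out[i] = ((double)(z >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  return out;
}
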