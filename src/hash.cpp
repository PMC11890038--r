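#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Seeded 64-bit FNV-1a over the k-mer string, mixed with splitmix64 and
// truncated to 53 bits so every value is exactly representable in a double.
// [[Rcpp::export]]
NumericVector hash_kmers_cpp(CharacterVector kmers, double seed) {
  const uint64_t FNV_OFFSET = 14695981039346656037ULL;
  const uint64_t FNV_PRIME = 1099511628211ULL;
  const uint64_t sd = splitmix64((uint64_t)seed);
  R_xlen_t n = kmers.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    uint64_t h = FNV_OFFSET ^ sd;
    for (; *s; ++s) {
      h ^= (uint64_t)(unsigned char)(*s);
      h *= FNV_PRIME;
    }
    out[i] = (double)(splitmix64(h) >> 11);
  }
  return out;
}
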