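#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 64-bit finaliser (splitmix64); applied to the 2-bit k-mer code XORed with
// the sketch seed so databases built with different seeds are incompatible
// by construction.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Bottom-s MinHash sketch over canonical k-mers of one or more contigs.
// K-mers containing non-ACGT characters are skipped; hashes are distinct
// and returned ascending. Values are truncated to 53 bits so they remain
// exact in R doubles. k must be <= 31.
// [[Rcpp::export]]
NumericVector sketch_hashes_cpp(CharacterVector contigs, int k, int s, double seed) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  uint64_t sd = (uint64_t) seed;
  uint64_t mask = (1ULL << (2 * k)) - 1;
  std::vector<uint64_t> hashes;
  for (int ci = 0; ci < contigs.size(); ++ci) {
    const char *seq = CHAR(STRING_ELT(contigs, ci));
    size_t n = strlen(seq);
    if (n < (size_t) k) continue;
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (size_t i = 0; i < n; ++i) {
      int b = base2bit(seq[i]);
      if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t) b) & mask;
      rev = (rev >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
      if (++valid >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        hashes.push_back(mix64(canon ^ sd) >> 11);
      }
    }
  }
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  size_t keep = std::min((size_t) s, hashes.size());
  NumericVector out(keep);
  for (size_t i = 0; i < keep; ++i) out[i] = (double) hashes[i];
  return out;
}

// Count of distinct canonical k-mers (oracle support for sketch tests).
// [[Rcpp::export]]
double count_canonical_kmers_cpp(CharacterVector contigs, int k, double seed) {
  NumericVector all = sketch_hashes_cpp(contigs, k, INT_MAX, seed);
  return (double) all.size();
}
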