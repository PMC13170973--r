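// Bottom-s MinHash sketch of canonical k-mers with multiplicities.
//
// Each k-length window free of non-ACGT letters is canonicalised
// (lexicographic min of the k-mer and its reverse complement; with the
// 2-bit encoding A<C<G<T that is the numeric min of the two codes) and
// hashed with a splitmix64 finalizer truncated to 53 bits so hash values
// are exactly representable as R doubles. Multiplicities are counted for
// every distinct canonical k-mer; the sketch keeps the s smallest hashes
// among k-mers seen at least m times.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

static inline int baseCode(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// [[Rcpp::export(name = ".sketchKmersCpp")]]
List sketchKmersCpp(CharacterVector seqs, int k, int s, int m, double seed) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  const uint64_t mask = (k == 31) ? ((~0ULL) >> 2) : ((1ULL << (2 * k)) - 1);
  const uint64_t hmask = (1ULL << 53) - 1;  // 53-bit hash space: exact doubles
  const uint64_t seedMix = splitmix64((uint64_t)seed + 0x5eedULL);

  std::unordered_map<uint64_t, int> counts;
  long double totalKmers = 0;

  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char *str = CHAR(STRING_ELT(seqs, i));
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (const char *p = str; *p; ++p) {
      int c = baseCode(*p);
      if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      if (++valid >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        uint64_t h = splitmix64(canon ^ seedMix) & hmask;
        ++counts[h];
        totalKmers += 1;
      }
    }
  }

  std::vector<std::pair<uint64_t, int> > retained;
  retained.reserve(counts.size());
  for (std::unordered_map<uint64_t, int>::const_iterator it = counts.begin();
       it != counts.end(); ++it) {
    if (it->second >= m) retained.push_back(*it);
  }
  std::sort(retained.begin(), retained.end());

  const size_t keep = std::min((size_t)s, retained.size());
  NumericVector hashes(keep);
  IntegerVector mult(keep);
  for (size_t i = 0; i < keep; ++i) {
    hashes[i] = (double)retained[i].first;
    mult[i] = retained[i].second;
  }
  return List::create(
    _["hashes"] = hashes,
    _["multiplicities"] = mult,
    _["distinct_retained"] = (double)retained.size(),
    _["distinct_total"] = (double)counts.size(),
    _["total_kmers"] = (double)totalKmers);
}
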