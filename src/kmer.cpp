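#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Depth histogram of distinct canonical k-mers across a set of reads.
// k <= 31 so a k-mer packs into 64 bits at 2 bits/base (A=0,C=1,G=2,T=3,
// most-significant base first, so numeric order == lexicographic order).
// Windows containing non-ACGT symbols are skipped.
// [[Rcpp::export]]
DataFrame cpp_kmer_spectrum(CharacterVector reads, int k) {
  if (k < 3 || k > 31) stop("k must be between 3 and 31");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  std::unordered_map<uint64_t, uint32_t> tab;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    SEXP el = STRING_ELT(reads, i);
    if (el == NA_STRING) continue;
    const char *s = CHAR(el);
    const int len = LENGTH(el);
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (int j = 0; j < len; ++j) {
      int code;
      switch (s[j]) {
        case 'A': case 'a': code = 0; break;
        case 'C': case 'c': code = 1; break;
        case 'G': case 'g': code = 2; break;
        case 'T': case 't': code = 3; break;
        default: code = -1;
      }
      if (code < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)code) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - code) << shift);
      if (++valid >= k) {
        const uint64_t canon = fwd < rev ? fwd : rev;
        ++tab[canon];
      }
    }
  }
  std::unordered_map<uint32_t, uint32_t> hist;
  for (const auto &kv : tab) ++hist[kv.second];
  std::vector<uint32_t> depths;
  depths.reserve(hist.size());
  for (const auto &kv : hist) depths.push_back(kv.first);
  std::sort(depths.begin(), depths.end());
  const R_xlen_t m = depths.size();
  IntegerVector d(m), n(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    d[i] = (int)depths[i];
    n[i] = (int)hist[depths[i]];
  }
  return DataFrame::create(_["depth"] = d, _["count"] = n);
}
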