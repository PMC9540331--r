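#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Canonical k-mer histogram over a set of read sequences.
// 2-bit rolling encoding (A=0,C=1,G=2,T=3, first base in the high bits, so
// integer order == lexicographic order); windows containing non-ACGT
// characters are skipped; each window contributes one instance of the
// lexicographic minimum of itself and its reverse complement.
// Returns multiplicity -> number of distinct canonical k-mers, plus the
// total instance count. Requires 1 <= k <= 31 (enforced in R).
// [[Rcpp::export]]
List cpp_kmer_histogram(CharacterVector reads, int k) {
  std::unordered_map<uint64_t, uint32_t> tab;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift = 2 * (k - 1);
  double total = 0.0;

  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    SEXP s = STRING_ELT(reads, i);
    if (s == NA_STRING) continue;
    const char *p = CHAR(s);
    const int len = LENGTH(s);
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (int j = 0; j < len; ++j) {
      int c;
      switch (p[j]) {
        case 'A': case 'a': c = 0; break;
        case 'C': case 'c': c = 1; break;
        case 'G': case 'g': c = 2; break;
        case 'T': case 't': c = 3; break;
        default: c = -1;
      }
      if (c < 0) { run = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
      if (++run >= k) {
        const uint64_t canon = fwd < rev ? fwd : rev;
        ++tab[canon];
        total += 1.0;
      }
    }
  }

  std::unordered_map<uint32_t, double> hist;
  for (const auto &kv : tab) hist[kv.second] += 1.0;
  std::vector<uint32_t> mult;
  mult.reserve(hist.size());
  for (const auto &kv : hist) mult.push_back(kv.first);
  std::sort(mult.begin(), mult.end());

  IntegerVector m(mult.size());
  NumericVector cnt(mult.size());
  for (size_t i = 0; i < mult.size(); ++i) {
    m[i] = (int)mult[i];
    cnt[i] = hist[mult[i]];
  }
  return List::create(_["multiplicity"] = m, _["count"] = cnt,
                      _["total_instances"] = total);
}
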