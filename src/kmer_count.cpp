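#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit encoding A=0, C=1, G=2, T=3. Packing the first base into the most
// significant bits makes numeric order on codes identical to lexicographic
// order on the k-mer strings, so canonical = min(code(fwd), code(revcomp)).
// Keys are returned as doubles; exact for 2k <= 52 bits, i.e. k <= 26.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// [[Rcpp::export]]
List count_kmers_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 26) stop("k must be between 1 and 26");
  const uint64_t mask = (((uint64_t)1) << (2 * k)) - 1;
  const int shift_rc = 2 * (k - 1);

  std::unordered_map<uint64_t, int> tab;
  double total = 0.0, possible = 0.0;

  double bases = 0.0;
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    if (seqs[s] != NA_STRING) bases += (double)LENGTH(STRING_ELT(seqs, s));
  }
  // distinct k-mers are bounded by total windows; cap the reservation
  size_t reserve = (size_t)std::min(bases, 8.0e6);
  tab.reserve(reserve);

  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    if (seqs[s] == NA_STRING) continue;
    const char *str = CHAR(STRING_ELT(seqs, s));
    R_xlen_t n = LENGTH(STRING_ELT(seqs, s));
    if (n >= k) possible += (double)(n - k + 1);
    uint64_t fwd = 0, rc = 0;
    int valid = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      int c = base_code(str[i]);
      if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - c) << shift_rc);
      if (++valid >= k) {
        uint64_t key = fwd < rc ? fwd : rc;
        ++tab[key];
        total += 1.0;
      }
    }
  }

  std::vector<std::pair<uint64_t, int> > flat(tab.begin(), tab.end());
  std::sort(flat.begin(), flat.end());
  R_xlen_t m = (R_xlen_t)flat.size();
  NumericVector keys(m);
  IntegerVector counts(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    keys[i] = (double)flat[i].first;
    counts[i] = flat[i].second;
  }
  return List::create(_["key"] = keys, _["count"] = counts,
                      _["total"] = total, _["skipped"] = possible - total);
}

// [[Rcpp::export]]
CharacterVector decode_kmers_cpp(NumericVector keys, int k) {
  if (k < 1 || k > 26) stop("k must be between 1 and 26");
  static const char alpha[4] = {'A', 'C', 'G', 'T'};
  R_xlen_t n = keys.size();
  CharacterVector out(n);
  std::vector<char> buf(k + 1, '\0');
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t code = (uint64_t)keys[i];
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = alpha[code & 3];
      code >>= 2;
    }
    out[i] = std::string(buf.data(), k);
  }
  return out;
}
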