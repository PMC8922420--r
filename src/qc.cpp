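#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Kept length after removing the maximal 3' suffix in which every base has
// Phred quality strictly below threshold (qualities are Phred+33 strings).
// [[Rcpp::export]]
IntegerVector cpp_qual_keep_len(CharacterVector qual, int threshold) {
  int n = qual.size();
  IntegerVector out(n);
  for (int i = 0; i < n; i++) {
    const char *q = CHAR(STRING_ELT(qual, i));
    int L = (int)std::strlen(q);
    int k = L;
    while (k > 0 && (q[k - 1] - 33) < threshold) k--;
    out[i] = k;
  }
  return out;
}

// VecScreen-style stand-in: ungapped match of a read 3' suffix against an
// adapter prefix. A suffix of length o qualifies when o >= min_match and
// mismatches <= floor(max_mm_frac * o); the longest qualifying suffix over
// all adapters is removed. Returns the kept read length.
// [[Rcpp::export]]
IntegerVector cpp_adapter_keep_len(CharacterVector seq, CharacterVector adapters,
                                   int min_match, double max_mm_frac) {
  int n = seq.size(), na = adapters.size();
  std::vector<std::string> ad(na);
  for (int a = 0; a < na; a++) ad[a] = as<std::string>(adapters[a]);
  IntegerVector out(n);
  for (int i = 0; i < n; i++) {
    const char *s = CHAR(STRING_ELT(seq, i));
    int L = (int)std::strlen(s);
    int best = L;
    for (int a = 0; a < na; a++) {
      int alen = (int)ad[a].size();
      int maxo = std::min(L, alen);
      for (int o = maxo; o >= min_match; o--) {
        int allow = (int)std::floor(max_mm_frac * o);
        int mm = 0;
        for (int j = 0; j < o; j++) {
          if (s[L - o + j] != ad[a][j]) {
            mm++;
            if (mm > allow) break;
          }
        }
        if (mm <= allow) {
          if (L - o < best) best = L - o;
          break; // longest match for this adapter found
        }
      }
    }
    out[i] = best;
  }
  return out;
}
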