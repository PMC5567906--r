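#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// 3' adapter localisation: for each read, scan candidate start positions
// left to right; at position p the adapter prefix of length
// min(adapter length, bases remaining) is compared and accepted when the
// overlap is >= min_overlap with <= max_mm mismatches. The first accepted
// position wins, so a full-length adapter match at the true insert/adapter
// junction dominates short spurious matches near the read end.
// Returns the 0-based insert length (position of the adapter start),
// or -1 when no acceptable match exists.
// [[Rcpp::export]]
IntegerVector cpp_find_adapter(CharacterVector reads, std::string adapter,
                               int min_overlap = 6, int max_mm = 1) {
  int nr = reads.size();
  int alen = adapter.size();
  IntegerVector out(nr);
  for (int r = 0; r < nr; ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int n = LENGTH(STRING_ELT(reads, r));
    int hit = -1;
    for (int p = 0; p + min_overlap <= n; ++p) {
      int o = std::min(alen, n - p);
      int mm = 0;
      for (int i = 0; i < o && mm <= max_mm; ++i) {
        if (toupper(s[p + i]) != toupper(adapter[i])) ++mm;
      }
      if (mm <= max_mm) { hit = p; break; }
    }
    out[r] = hit;
  }
  return out;
}

// Does each sequence contain `pattern` (full length) with <= max_mm
// mismatches anywhere? Used for 5' adapter contamination screening.
// [[Rcpp::export]]
LogicalVector cpp_contains_pattern(CharacterVector seqs, std::string pattern,
                                   int max_mm = 1) {
  int nr = seqs.size();
  int plen = pattern.size();
  LogicalVector out(nr);
  for (int r = 0; r < nr; ++r) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    int n = LENGTH(STRING_ELT(seqs, r));
    bool found = false;
    for (int p = 0; p + plen <= n && !found; ++p) {
      int mm = 0;
      for (int i = 0; i < plen && mm <= max_mm; ++i) {
        if (toupper(s[p + i]) != toupper(pattern[i])) ++mm;
      }
      if (mm <= max_mm) found = true;
    }
    out[r] = found;
  }
  return out;
}
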