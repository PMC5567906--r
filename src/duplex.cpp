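#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Per-position pairing class of a miRNA base against a target base, read
// antiparallel: W = Watson-Crick, G = G.U wobble, M = mismatch.
static inline char norm_base(char c) {
  c = toupper(c);
  return (c == 'T') ? 'U' : c;
}

static inline char pair_class(char m, char t) {
  if ((m == 'A' && t == 'U') || (m == 'U' && t == 'A') ||
      (m == 'G' && t == 'C') || (m == 'C' && t == 'G'))
    return 'W';
  if ((m == 'G' && t == 'U') || (m == 'U' && t == 'G')) return 'G';
  return 'M';
}

static inline double class_weight(char c) {
  if (c == 'W') return 0.0;
  if (c == 'G') return 0.5;
  return 1.0;  // M or B
}

// Scan a transcript for antisense duplex windows against a miRNA.
// For every window start, the best-scoring gapped alignment (at most one
// single-nucleotide bulge on either strand, disallowed while flanking
// miRNA positions bulge_excl_lo..bulge_excl_hi) is computed; windows whose
// best score is <= max_score are returned. Scores: mismatch 1, G.U wobble
// 0.5, bulge 1. Coordinates are 0-based half-open on the transcript.
// [[Rcpp::export]]
DataFrame cpp_duplex_scan(std::string mirna, std::string transcript,
                          double max_score = 4.0, bool allow_bulge = true,
                          int bulge_excl_lo = 2, int bulge_excl_hi = 12) {
  int L = mirna.size();
  int n = transcript.size();
  std::vector<char> m(L), t(n);
  for (int i = 0; i < L; ++i) m[i] = norm_base(mirna[i]);
  for (int i = 0; i < n; ++i) t[i] = norm_base(transcript[i]);

  std::vector<int> out_start, out_end, out_bside, out_bpos;
  std::vector<double> out_score;
  std::vector<std::string> out_cls;

  std::string cls(L, '.'), best_cls(L, '.');

  for (int s = 0; s + L <= n; ++s) {
    double best = 1e9;
    int best_bside = 0, best_bpos = 0, best_len = L;

    // ungapped: miRNA position i (1-based) pairs transcript s + L - i
    {
      double sc = 0.0;
      for (int i = 1; i <= L; ++i) {
        cls[i - 1] = pair_class(m[i - 1], t[s + L - i]);
        sc += class_weight(cls[i - 1]);
      }
      best = sc; best_cls = cls; best_bside = 0; best_bpos = 0; best_len = L;
    }

    if (allow_bulge) {
      // target-side bulge after miRNA position k: window length L + 1
      if (s + L + 1 <= n) {
        for (int k = 1; k <= L - 1; ++k) {
          if (k >= bulge_excl_lo - 1 && k <= bulge_excl_hi) continue;
          double sc = 1.0;  // bulged target base
          for (int i = 1; i <= L; ++i) {
            int tp = (i <= k) ? (s + L + 1 - i) : (s + L - i);
            cls[i - 1] = pair_class(m[i - 1], t[tp]);
            sc += class_weight(cls[i - 1]);
          }
          if (sc < best) {
            best = sc; best_cls = cls; best_bside = 2; best_bpos = k;
            best_len = L + 1;
          }
        }
      }
      // miRNA-side bulge at position b: window length L - 1
      if (s + L - 1 <= n) {
        for (int b = 1; b <= L; ++b) {
          if (b >= bulge_excl_lo && b <= bulge_excl_hi) continue;
          double sc = 1.0;  // bulged miRNA base
          for (int i = 1; i <= L; ++i) {
            if (i == b) { cls[i - 1] = 'B'; continue; }
            int tp = (i < b) ? (s + L - 1 - i) : (s + L - i);
            cls[i - 1] = pair_class(m[i - 1], t[tp]);
            sc += class_weight(cls[i - 1]);
          }
          if (sc < best) {
            best = sc; best_cls = cls; best_bside = 1; best_bpos = b;
            best_len = L - 1;
          }
        }
      }
    }

    if (best <= max_score) {
      out_start.push_back(s);
      out_end.push_back(s + best_len);
      out_score.push_back(best);
      out_cls.push_back(best_cls);
      out_bside.push_back(best_bside);
      out_bpos.push_back(best_bpos);
    }
  }

  return DataFrame::create(
      _["start"] = out_start, _["end"] = out_end, _["score"] = out_score,
      _["classes"] = out_cls, _["bulge_side"] = out_bside,
      _["bulge_pos"] = out_bpos, _["stringsAsFactors"] = false);
}
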