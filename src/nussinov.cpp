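#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// RNA/DNA alphabet handled uniformly: T is read as U.
static inline char norm_base(char c) {
  c = toupper(c);
  return (c == 'T') ? 'U' : c;
}

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Maximum base-pairing secondary structure (Nussinov DP) with a minimum
// hairpin loop of `min_loop` unpaired bases. Returns the dot-bracket
// structure and a pseudo-energy of -1.0 kcal/mol per pair.
// [[Rcpp::export]]
List cpp_nussinov(std::string seq, int min_loop = 3) {
  int n = seq.size();
  std::vector<char> s(n);
  for (int i = 0; i < n; ++i) s[i] = norm_base(seq[i]);

  if (n == 0) return List::create(_["structure"] = "", _["pairs"] = 0);

  // M[i][j]: max pairs in s[i..j]
  std::vector<std::vector<short> > M(n, std::vector<short>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      short best = M[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(s[i], s[k])) continue;
        short v = 1;
        if (k - i > min_loop + 1) v += M[i + 1][k - 1];
        if (k < j) v += M[k + 1][j];
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }

  // traceback
  std::string db(n, '.');
  std::stack<std::pair<int, int> > todo;
  todo.push(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    std::pair<int, int> seg = todo.top();
    todo.pop();
    int i = seg.first, j = seg.second;
    if (i >= j || j - i <= min_loop) continue;
    // among co-optimal structures prefer pairing i, and prefer the most
    // distant partner: long-range stems (hairpin arms) over local pairs
    bool paired = false;
    for (int k = j; k >= i + min_loop + 1; --k) {
      if (!can_pair(s[i], s[k])) continue;
      short v = 1;
      if (k - i > min_loop + 1) v += M[i + 1][k - 1];
      if (k < j) v += M[k + 1][j];
      if (v == M[i][j]) {
        db[i] = '(';
        db[k] = ')';
        if (k - i > min_loop + 1) todo.push(std::make_pair(i + 1, k - 1));
        if (k < j) todo.push(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) todo.push(std::make_pair(i + 1, j));
  }

  return List::create(_["structure"] = db, _["pairs"] = (int)M[0][n - 1]);
}
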