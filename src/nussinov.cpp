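#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Weighted base-pair maximisation (Nussinov-style) with a minimum
// hairpin-loop length. Input is RNA alphabet {A,C,G,U}; the character
// 'X' marks linker/sentinel positions that can never pair (used by the
// cofold-by-concatenation trick). Pairs spanning the cut region
// [cut_lo, cut_hi) are exempt from the hairpin constraint.

static inline int pair_score(char a, char b, int gc, int au, int gu) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return gc;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return au;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return gu;
  return -1; // disallowed
}

// [[Rcpp::export(name = ".cpp_nussinov")]]
List cpp_nussinov(std::string seq, int min_hairpin,
                  int score_gc, int score_au, int score_gu,
                  int cut_lo, int cut_hi) {
  const int n = (int)seq.size();
  std::vector<int> M((size_t)n * n, 0);
  auto at = [&](int i, int j) -> int& { return M[(size_t)i * n + j]; };

  auto allowed = [&](int i, int k) -> bool {
    if (seq[i] == 'X' || seq[k] == 'X') return false;
    if (pair_score(seq[i], seq[k], score_gc, score_au, score_gu) < 0)
      return false;
    if (k - i - 1 >= min_hairpin) return true;
    // across-the-cut pairs are not hairpin-constrained
    return (cut_lo >= 0 && i < cut_lo && k >= cut_hi);
  };

  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = at(i + 1 <= j ? i + 1 : j, j); // i unpaired (i+1 > j handled below)
      if (i + 1 > j) best = 0;
      for (int k = i + 1; k <= j; ++k) {
        if (!allowed(i, k)) continue;
        int s = pair_score(seq[i], seq[k], score_gc, score_au, score_gu);
        int inner = (i + 1 <= k - 1) ? at(i + 1, k - 1) : 0;
        int right = (k + 1 <= j) ? at(k + 1, j) : 0;
        int cand = s + inner + right;
        if (cand > best) best = cand;
      }
      at(i, j) = best;
    }
  }

  // deterministic traceback: at (i, j) prefer pairing i with the
  // smallest k achieving the optimum, else leave i unpaired
  std::string structure(n, '.');
  std::vector<int> pi, pj, pw;
  std::vector<std::pair<int, int>> stack;
  if (n > 1) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    int target = at(i, j);
    if (target == 0) continue;
    bool paired = false;
    for (int k = i + 1; k <= j; ++k) {
      if (!allowed(i, k)) continue;
      int s = pair_score(seq[i], seq[k], score_gc, score_au, score_gu);
      int inner = (i + 1 <= k - 1) ? at(i + 1, k - 1) : 0;
      int right = (k + 1 <= j) ? at(k + 1, j) : 0;
      if (s + inner + right == target) {
        structure[i] = '('; structure[k] = ')';
        pi.push_back(i); pj.push_back(k); pw.push_back(s);
        if (i + 1 <= k - 1) stack.push_back(std::make_pair(i + 1, k - 1));
        if (k + 1 <= j) stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }

  int total = (n > 1) ? at(0, n - 1) : 0;
  return List::create(_["score"] = total,
                      _["structure"] = structure,
                      _["pair_i"] = pi, _["pair_j"] = pj,
                      _["pair_score"] = pw);
}
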