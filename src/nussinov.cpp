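#include <Rcpp.h>
#include <vector>
#include <utility>

using namespace Rcpp;

// Watson-Crick plus GU wobble
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Base-pair maximization over nested pairings with a minimum hairpin size.
// A pair (k, j) (0-based) is admissible when j - k > min_hairpin.
// Returns a 1-based pair table (0 = unpaired). Traceback is deterministic:
// leave j unpaired when that attains the optimum, otherwise pair j with the
// smallest admissible k.
// [[Rcpp::export(name = ".nussinov_pairs")]]
IntegerVector nussinov_pairs(std::string seq, int min_hairpin) {
  const int n = (int) seq.size();
  IntegerVector pt(n);
  if (n == 0) return pt;

  std::vector< std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int span = min_hairpin + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      const int j = i + span;
      int best = M[i][j - 1];
      for (int k = i; k <= j - min_hairpin - 1; ++k) {
        if (!can_pair(seq[k], seq[j])) continue;
        int v = 1;
        if (k > i) v += M[i][k - 1];
        if (k + 1 <= j - 1) v += M[k + 1][j - 1];
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }

  std::vector< std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    const int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i <= min_hairpin) continue;
    if (M[i][j] == M[i][j - 1]) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - min_hairpin - 1; ++k) {
      if (!can_pair(seq[k], seq[j])) continue;
      int v = 1;
      if (k > i) v += M[i][k - 1];
      if (k + 1 <= j - 1) v += M[k + 1][j - 1];
      if (v == M[i][j]) {
        pt[k] = j + 1;
        pt[j] = k + 1;
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
  return pt;
}
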