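#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with match = 1, mismatch = 0,
// linear gap = -1. Among score-optimal alignments the one with the most
// identical positions is taken; given (score, matches) the number of
// alignment columns is fully determined, so the result is deterministic.
static void align_pair(const std::string &a, const std::string &b,
                       int &score, int &matches, int &columns) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> S((n + 1) * (m + 1)), M((n + 1) * (m + 1));
  const int W = m + 1;
  S[0] = 0; M[0] = 0;
  for (int j = 1; j <= m; ++j) { S[j] = -j; M[j] = 0; }
  for (int i = 1; i <= n; ++i) {
    S[i * W] = -i; M[i * W] = 0;
    for (int j = 1; j <= m; ++j) {
      const int mt = (a[i - 1] == b[j - 1]) ? 1 : 0;
      int bs = S[(i - 1) * W + (j - 1)] + mt;
      int bm = M[(i - 1) * W + (j - 1)] + mt;
      int s2 = S[(i - 1) * W + j] - 1, m2 = M[(i - 1) * W + j];
      if (s2 > bs || (s2 == bs && m2 > bm)) { bs = s2; bm = m2; }
      s2 = S[i * W + (j - 1)] - 1; m2 = M[i * W + (j - 1)];
      if (s2 > bs || (s2 == bs && m2 > bm)) { bs = s2; bm = m2; }
      S[i * W + j] = bs;
      M[i * W + j] = bm;
    }
  }
  score = S[n * W + m];
  matches = M[n * W + m];
  // gap columns = matches - score; aligned pairs = (n + m - gapcols) / 2
  const int gapcols = matches - score;
  const int pairs = (n + m - gapcols) / 2;
  columns = pairs + gapcols;
}

// [[Rcpp::export]]
List cpp_alignment_stats(std::string a, std::string b) {
  int score, matches, columns;
  align_pair(a, b, score, matches, columns);
  return List::create(_["score"] = score, _["matches"] = matches,
                      _["columns"] = columns);
}

// [[Rcpp::export]]
NumericVector cpp_identity(CharacterVector a, CharacterVector b) {
  const R_xlen_t n = a.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[i]), sb = as<std::string>(b[i]);
    int score, matches, columns;
    align_pair(sa, sb, score, matches, columns);
    const double denom = (double)std::max(sa.size(), sb.size());
    out[i] = matches / denom;
  }
  return out;
}

// identity of one query against many subjects (greedy clustering inner loop)
// [[Rcpp::export]]
NumericVector cpp_identity_one_many(std::string a, CharacterVector ys) {
  const R_xlen_t n = ys.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sb = as<std::string>(ys[i]);
    int score, matches, columns;
    align_pair(a, sb, score, matches, columns);
    out[i] = matches / (double)std::max(a.size(), sb.size());
  }
  return out;
}
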