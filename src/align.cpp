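#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment identity: match +1, mismatch -1,
// gap -2 (linear). Identity = matching columns / total alignment columns,
// terminal gaps included. Among equal-score alignments the one with the
// most matches (then the fewest columns) defines the identity, making the
// value independent of traceback order.

struct Cell {
  int score;
  int matches;
  int cols;
};

static inline bool better(const Cell &a, const Cell &b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.matches != b.matches) return a.matches > b.matches;
  return a.cols < b.cols;
}

static double nw_identity_one(const std::string &a, const std::string &b) {
  const int GAP = -2, MATCH = 1, MISMATCH = -1;
  int n = a.size(), m = b.size();
  std::vector<Cell> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = {GAP * j, 0, j};
  for (int i = 1; i <= n; ++i) {
    cur[0] = {GAP * i, 0, i};
    for (int j = 1; j <= m; ++j) {
      bool eq = a[i - 1] == b[j - 1];
      Cell diag = {prev[j - 1].score + (eq ? MATCH : MISMATCH),
                   prev[j - 1].matches + (eq ? 1 : 0),
                   prev[j - 1].cols + 1};
      Cell up = {prev[j].score + GAP, prev[j].matches, prev[j].cols + 1};
      Cell left = {cur[j - 1].score + GAP, cur[j - 1].matches,
                   cur[j - 1].cols + 1};
      Cell best = diag;
      if (better(up, best)) best = up;
      if (better(left, best)) best = left;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return static_cast<double>(prev[m].matches) /
         static_cast<double>(prev[m].cols);
}

// [[Rcpp::export(name = ".nw_identity_many")]]
NumericVector nw_identity_many(CharacterVector seqs, std::string ref) {
  int n = seqs.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    out[k] = nw_identity_one(as<std::string>(seqs[k]), ref);
  }
  return out;
}
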