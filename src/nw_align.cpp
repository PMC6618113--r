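#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Needleman-Wunsch global alignment with affine gaps.
// Scoring: match/mismatch scores; a gap of length k costs
// gap_open + k * gap_extend (penalties passed as positive numbers).
// Returns score, matched columns, total alignment columns, and columns
// excluding terminal gap runs (usearch_global-style identity denominator).

static const int NEG = std::numeric_limits<int>::min() / 4;

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match = 1, double mismatch = -1,
                  double gap_open = 5, double gap_extend = 2) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  // integer scoring scaled by 2 to allow half scores if ever needed
  const int sm = (int)(match * 2), sx = (int)(mismatch * 2);
  const int go = (int)(gap_open * 2), ge = (int)(gap_extend * 2);

  // M: end in match/mismatch; X: gap in b (consume a); Y: gap in a
  std::vector<std::vector<int>> M(n + 1, std::vector<int>(m + 1, NEG));
  std::vector<std::vector<int>> X(n + 1, std::vector<int>(m + 1, NEG));
  std::vector<std::vector<int>> Y(n + 1, std::vector<int>(m + 1, NEG));
  M[0][0] = 0;
  for (int i = 1; i <= n; ++i) X[i][0] = -(go + ge * i);
  for (int j = 1; j <= m; ++j) Y[0][j] = -(go + ge * j);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int s = (a[i - 1] == b[j - 1]) ? sm : sx;
      int best_prev = std::max(M[i - 1][j - 1],
                      std::max(X[i - 1][j - 1], Y[i - 1][j - 1]));
      M[i][j] = best_prev + s;
      X[i][j] = std::max(M[i - 1][j] - (go + ge),
                std::max(X[i - 1][j] - ge, Y[i - 1][j] - (go + ge)));
      Y[i][j] = std::max(M[i][j - 1] - (go + ge),
                std::max(Y[i][j - 1] - ge, X[i][j - 1] - (go + ge)));
    }
  }

  // traceback
  int i = n, j = m;
  int state; // 0 = M, 1 = X, 2 = Y
  {
    int best = M[n][m]; state = 0;
    if (X[n][m] > best) { best = X[n][m]; state = 1; }
    if (Y[n][m] > best) { best = Y[n][m]; state = 2; }
  }
  const int final_score = std::max(M[n][m], std::max(X[n][m], Y[n][m]));

  std::string ops; // 'M' aligned pair, 'X' gap in b, 'Y' gap in a
  while (i > 0 || j > 0) {
    if (state == 0) {
      int s = (a[i - 1] == b[j - 1]) ? sm : sx;
      int prev = M[i][j] - s;
      ops.push_back('M');
      if (prev == M[i - 1][j - 1]) state = 0;
      else if (prev == X[i - 1][j - 1]) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      ops.push_back('X');
      if (i == 1 && j == 0) { --i; break; }
      int cur = X[i][j];
      if (cur == X[i - 1][j] - ge) state = 1;
      else if (cur == M[i - 1][j] - (go + ge)) state = 0;
      else state = 2;
      --i;
    } else {
      ops.push_back('Y');
      if (j == 1 && i == 0) { --j; break; }
      int cur = Y[i][j];
      if (cur == Y[i][j - 1] - ge) state = 2;
      else if (cur == M[i][j - 1] - (go + ge)) state = 0;
      else state = 1;
      --j;
    }
    if (i == 0 && j > 0) { while (j > 0) { ops.push_back('Y'); --j; } }
    if (j == 0 && i > 0 && state != 1) { while (i > 0) { ops.push_back('X'); --i; } }
  }
  std::reverse(ops.begin(), ops.end());

  // walk the alignment for matches and gap-trimmed column count
  int cols = ops.size();
  int lead = 0, trail = 0;
  while (lead < cols && ops[lead] != 'M') ++lead;
  while (trail < cols - lead && ops[cols - 1 - trail] != 'M') ++trail;
  int matches = 0;
  int ai = 0, bj = 0;
  for (int k = 0; k < cols; ++k) {
    if (ops[k] == 'M') {
      if (a[ai] == b[bj]) ++matches;
      ++ai; ++bj;
    } else if (ops[k] == 'X') ++ai;
    else ++bj;
  }
  int cols_trimmed = cols - lead - trail;

  return List::create(
    _["score"] = final_score / 2.0,
    _["matches"] = matches,
    _["columns"] = cols,
    _["columns_trimmed"] = cols_trimmed,
    _["cigar_ops"] = ops
  );
}
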