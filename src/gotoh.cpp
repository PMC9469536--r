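#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Global pairwise alignment with affine gaps (Needleman-Wunsch / Gotoh).
// Scoring: match / mismatch per column; a gap run of length L costs
// gap_open + gap_extend * (L - 1) (both passed as negative scores, so the
// first gap column scores gap_open and each further column gap_extend).
// Tie-breaking in the traceback prefers the diagonal, then up (gap in B,
// consuming A), then left (gap in A), which makes the optimal alignment
// deterministic.

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b,
                 double match, double mismatch,
                 double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  // M: last column aligned a[i] with b[j]; X: gap in B (A consumed);
  // Y: gap in A (B consumed)
  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double>> X(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double>> Y(n + 1, std::vector<double>(m + 1, NEG));
  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i][0] = gap_open + gap_extend * (i - 1);
  for (int j = 1; j <= m; ++j) Y[0][j] = gap_open + gap_extend * (j - 1);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double prev = std::max(M[i - 1][j - 1],
                             std::max(X[i - 1][j - 1], Y[i - 1][j - 1]));
      M[i][j] = prev + s;
      X[i][j] = std::max(X[i - 1][j] + gap_extend,
                         std::max(M[i - 1][j], Y[i - 1][j]) + gap_open);
      Y[i][j] = std::max(Y[i][j - 1] + gap_extend,
                         std::max(M[i][j - 1], X[i][j - 1]) + gap_open);
    }
  }
  double best = std::max(M[n][m], std::max(X[n][m], Y[n][m]));

  // traceback; state 0 = M, 1 = X (up), 2 = Y (left); preference M > X > Y
  std::string ra, rb;
  int i = n, j = m;
  int state;
  if (best == M[n][m]) state = 0;
  else if (best == X[n][m]) state = 1;
  else state = 2;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) { // shouldn't happen except at origin
        state = (i > 0) ? 1 : 2;
        continue;
      }
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double target = M[i][j] - s;
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[i][j] == target) state = 0;
      else if (X[i][j] == target) state = 1;
      else state = 2;
    } else if (state == 1) { // gap in B, consume a[i]
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      double v = X[i][j];
      --i;
      if (M[i][j] + gap_open == v && j > 0) state = 0;
      else if (X[i][j] + gap_extend == v) state = 1;
      else if (Y[i][j] + gap_open == v) state = 2;
      else state = 0; // boundary: M[0][0]
    } else { // gap in A, consume b[j]
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      double v = Y[i][j];
      --j;
      if (M[i][j] + gap_open == v && i > 0) state = 0;
      else if (Y[i][j] + gap_extend == v) state = 2;
      else if (X[i][j] + gap_open == v) state = 1;
      else state = 0;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = best);
}
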