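#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Gotoh dynamic programming for Needleman-Wunsch global alignment with
// affine gaps.  A gap of length L costs gap_open + (L - 1) * gap_extend
// (the opening column carries the opening penalty).  Three-state recurrence:
//   M  — residues aligned in both sequences
//   X  — gap in seq2 (consumes seq1; an "up" move in the DP table)
//   Y  — gap in seq1 (consumes seq2; a "left" move)
// X/Y may not open directly from each other: adjacent opposite gaps cost
// 2*gap_open, always worse than one mismatch under protein matrices.
// Ties prefer M over X over Y so the traceback (and hence the identity
// count) is deterministic across platforms.

static const int NEG = INT_MIN / 4;

// [[Rcpp::export]]
List nw_align_cpp(IntegerVector s1, IntegerVector s2, IntegerMatrix sub,
                  int gap_open, int gap_extend) {
  const int n = s1.size(), m = s2.size();
  const size_t w = (size_t)m + 1;
  std::vector<int> M((n + 1) * w, NEG), X((n + 1) * w, NEG),
      Y((n + 1) * w, NEG);
  // traceback source state per cell: 0 = M, 1 = X, 2 = Y
  std::vector<unsigned char> tM((n + 1) * w, 0), tX((n + 1) * w, 0),
      tY((n + 1) * w, 0);
  M[0] = 0;
  for (int i = 1; i <= n; ++i) {
    X[i * w] = -gap_open - (i - 1) * gap_extend;
    tX[i * w] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -gap_open - (j - 1) * gap_extend;
    tY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    const size_t r = i * w, p = (i - 1) * w;
    const int ci = s1[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int s = sub(ci, s2[j - 1]);
      // M: diagonal move from best of the three states
      int best = M[p + j - 1];
      unsigned char src = 0;
      if (X[p + j - 1] > best) { best = X[p + j - 1]; src = 1; }
      if (Y[p + j - 1] > best) { best = Y[p + j - 1]; src = 2; }
      M[r + j] = (best <= NEG) ? NEG : best + s;
      tM[r + j] = src;
      // X: consume seq1 (gap column in seq2)
      int xo = (M[p + j] <= NEG) ? NEG : M[p + j] - gap_open;
      int xe = (X[p + j] <= NEG) ? NEG : X[p + j] - gap_extend;
      if (xo >= xe) { X[r + j] = xo; tX[r + j] = 0; }
      else          { X[r + j] = xe; tX[r + j] = 1; }
      // Y: consume seq2 (gap column in seq1)
      int yo = (M[r + j - 1] <= NEG) ? NEG : M[r + j - 1] - gap_open;
      int ye = (Y[r + j - 1] <= NEG) ? NEG : Y[r + j - 1] - gap_extend;
      if (yo >= ye) { Y[r + j] = yo; tY[r + j] = 0; }
      else          { Y[r + j] = ye; tY[r + j] = 2; }
    }
  }
  const size_t end = (size_t)n * w + m;
  int score = M[end];
  unsigned char state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  int i = n, j = m, identities = 0, length = 0;
  while (i > 0 || j > 0) {
    const size_t c = (size_t)i * w + j;
    ++length;
    if (state == 0) {
      if (s1[i - 1] == s2[j - 1]) ++identities;
      state = tM[c];
      --i; --j;
    } else if (state == 1) {
      state = tX[c];
      --i;
    } else {
      state = tY[c];
      --j;
    }
  }
  return List::create(_["score"] = score, _["alignment_length"] = length,
                      _["identities"] = identities);
}
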