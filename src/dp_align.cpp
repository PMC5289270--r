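#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Sequential (monotone) residue-pair alignment by dynamic programming.
//
// Objective: sum of S[i,j] over aligned pairs minus `gap_open` per internal
// gap opening on either chain (no extension penalty); unaligned ends are
// free. Three states (match, skip-in-A, skip-in-B); ties are resolved
// toward the diagonal (the match state wins equal comparisons).
//
// S: n x m non-negative similarity matrix. Returns a k x 2 matrix of
// 1-based aligned indices, strictly increasing in both columns.
// [[Rcpp::export]]
IntegerMatrix dp_align_cpp(NumericMatrix S, double gap_open = 0.6) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e18;
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), Ix((n + 1) * W, NEG),
      Iy((n + 1) * W, NEG);
  // traceback codes: in M: 0=from M,1=from Ix,2=from Iy,3=fresh start
  // in Ix: 0=from M,1=from Ix,2=from Iy (all at i-1,j)
  // in Iy: 0=from M,1=from Iy,2=from Ix (all at i,j-1)
  std::vector<signed char> Mp((n + 1) * W, -1), Ixp((n + 1) * W, -1),
      Iyp((n + 1) * W, -1);

  double best = NEG;
  int bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1);
      // match state: prefer continuing from M on ties (diagonal bias)
      double v = M[d];
      signed char p = 0;
      if (Ix[d] > v) { v = Ix[d]; p = 1; }
      if (Iy[d] > v) { v = Iy[d]; p = 2; }
      if (0.0 > v) { v = 0.0; p = 3; }
      M[c] = S(i - 1, j - 1) + v;
      Mp[c] = p;
      if (M[c] > best) { best = M[c]; bi = i; bj = j; }
      // skip A_i (gap in B): from row i-1, same j
      const int up = (i - 1) * W + j;
      double vx = M[up] - gap_open;
      signed char px = 0;
      if (Ix[up] > vx) { vx = Ix[up]; px = 1; }
      if (Iy[up] - gap_open > vx) { vx = Iy[up] - gap_open; px = 2; }
      Ix[c] = vx;
      Ixp[c] = px;
      // skip B_j (gap in A): from same i, col j-1
      const int lf = i * W + (j - 1);
      double vy = M[lf] - gap_open;
      signed char py = 0;
      if (Iy[lf] > vy) { vy = Iy[lf]; py = 1; }
      if (Ix[lf] - gap_open > vy) { vy = Ix[lf] - gap_open; py = 2; }
      Iy[c] = vy;
      Iyp[c] = py;
    }
  }
  if (bi < 0) return IntegerMatrix(0, 2);

  std::vector<int> ai, bj2;
  int i = bi, j = bj, state = 0; // 0=M,1=Ix,2=Iy
  while (i >= 1 && j >= 1) {
    const int c = i * W + j;
    if (state == 0) {
      ai.push_back(i);
      bj2.push_back(j);
      signed char p = Mp[c];
      if (p == 3) break;
      state = p;
      --i; --j;
    } else if (state == 1) {
      state = Ixp[c];
      --i;
    } else {
      signed char p = Iyp[c];
      state = (p == 0) ? 0 : (p == 1 ? 2 : 1);
      --j;
    }
  }
  const int k = ai.size();
  IntegerMatrix out(k, 2);
  for (int r = 0; r < k; ++r) {
    out(r, 0) = ai[k - 1 - r];
    out(r, 1) = bj2[k - 1 - r];
  }
  return out;
}
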