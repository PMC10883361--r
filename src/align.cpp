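#include <Rcpp.h>
using namespace Rcpp;

// Profile-profile global alignment (Gotoh affine-gap DP).
//
// A and B are S x La / S x Lb column-frequency profiles (rows = states in a
// fixed order, last row = gap fraction). The score of aligning column i of A
// with column j of B is sum_{a,b < S-1} A(a,i) * B(b,j) * sub(a,b); gap
// fractions inside a profile column score 0. A gap of length L inserted into
// either profile costs gap_open + L * gap_ext.
//
// Returns a 2 x Lmerged integer matrix of 1-based source-column indices
// (0 = gap) describing the merged alignment.
// [[Rcpp::export(name = ".profile_align")]]
IntegerMatrix profile_align(NumericMatrix A, NumericMatrix B,
                            NumericMatrix sub, double gap_open,
                            double gap_ext) {
  const int S = A.nrow() - 1;  // substitution states (last row = gap)
  const int la = A.ncol(), lb = B.ncol();
  const double NEG = -1e30;

  // column-pair substitution scores
  NumericMatrix cs(la, lb);
  for (int i = 0; i < la; ++i)
    for (int j = 0; j < lb; ++j) {
      double s = 0.0;
      for (int a = 0; a < S; ++a) {
        if (A(a, i) == 0.0) continue;
        for (int b = 0; b < S; ++b)
          if (B(b, j) != 0.0) s += A(a, i) * B(b, j) * sub(a, b);
      }
      cs(i, j) = s;
    }

  NumericMatrix M(la + 1, lb + 1), X(la + 1, lb + 1), Y(la + 1, lb + 1);
  // X: gap in B (A column vs gap), Y: gap in A
  M(0, 0) = 0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= la; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -gap_open - gap_ext * i;
  }
  for (int j = 1; j <= lb; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -gap_open - gap_ext * j;
  }
  for (int i = 1; i <= la; ++i)
    for (int j = 1; j <= lb; ++j) {
      double best = std::max(M(i - 1, j - 1),
                             std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = best + cs(i - 1, j - 1);
      X(i, j) = std::max(M(i - 1, j) - gap_open - gap_ext,
                         X(i - 1, j) - gap_ext);
      Y(i, j) = std::max(M(i, j - 1) - gap_open - gap_ext,
                         Y(i, j - 1) - gap_ext);
    }

  // traceback (prefer M, then X, then Y on ties: deterministic)
  std::vector<int> ai, bi;
  int i = la, j = lb;
  int state;  // 0 = M, 1 = X, 2 = Y
  double m = M(i, j), x = X(i, j), y = Y(i, j);
  state = (m >= x && m >= y) ? 0 : (x >= y ? 1 : 2);
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      double prevM = M(i - 1, j - 1), prevX = X(i - 1, j - 1),
             prevY = Y(i - 1, j - 1);
      state = (prevM >= prevX && prevM >= prevY) ? 0 : (prevX >= prevY ? 1 : 2);
      --i; --j;
    } else if (state == 1) {
      ai.push_back(i); bi.push_back(0);
      state = (M(i - 1, j) - gap_open - gap_ext >= X(i - 1, j) - gap_ext) ? 0 : 1;
      --i;
    } else {
      ai.push_back(0); bi.push_back(j);
      state = (M(i, j - 1) - gap_open - gap_ext >= Y(i, j - 1) - gap_ext) ? 0 : 2;
      --j;
    }
  }
  const int L = ai.size();
  IntegerMatrix out(2, L);
  for (int k = 0; k < L; ++k) {
    out(0, k) = ai[L - 1 - k];
    out(1, k) = bi[L - 1 - k];
  }
  return out;
}
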