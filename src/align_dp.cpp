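#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap (Gotoh) global alignment over a precomputed column-score
// matrix S (nrow = columns of A, ncol = columns of B). A gap of length k
// costs gap_open + (k-1) * gap_extend (both are scores, <= 0). End gaps are
// charged. Returns the optimal score and a traceback of moves
// (0 = diagonal, 1 = column from A only, 2 = column from B only), in
// alignment order.
// [[Rcpp::export(name = ".gotoh_dp")]]
List gotoh_dp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e300;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // X: gap in B (consume A column); Y: gap in A (consume B column)
  M(0, 0) = 0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = gap_open + (i - 1) * gap_extend;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = gap_open + (j - 1) * gap_extend;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double prev = std::max(M(i - 1, j - 1),
                             std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = prev + S(i - 1, j - 1);
      X(i, j) = std::max(std::max(M(i - 1, j) + gap_open,
                                  X(i - 1, j) + gap_extend),
                         Y(i - 1, j) + gap_open);
      Y(i, j) = std::max(std::max(M(i, j - 1) + gap_open,
                                  Y(i, j - 1) + gap_extend),
                         X(i, j - 1) + gap_open);
    }
  }
  double best = std::max(M(n, m), std::max(X(n, m), Y(n, m)));
  // traceback; prefer diagonal, then X, then Y on exact ties (determinism)
  std::vector<int> moves;
  int i = n, j = m;
  int state = (M(n, m) >= X(n, m) && M(n, m) >= Y(n, m)) ? 0
            : (X(n, m) >= Y(n, m) ? 1 : 2);
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      moves.push_back(0);
      double target = M(i, j) - S(i - 1, j - 1);
      --i; --j;
      state = (std::abs(M(i, j) - target) < eps) ? 0
            : (std::abs(X(i, j) - target) < eps ? 1 : 2);
    } else if (state == 1) {
      moves.push_back(1);
      double v = X(i, j);
      --i;
      if (std::abs(M(i, j) + gap_open - v) < eps) state = 0;
      else if (std::abs(X(i, j) + gap_extend - v) < eps) state = 1;
      else state = 2;
    } else {
      moves.push_back(2);
      double v = Y(i, j);
      --j;
      if (std::abs(M(i, j) + gap_open - v) < eps) state = 0;
      else if (std::abs(Y(i, j) + gap_extend - v) < eps) state = 2;
      else state = 1;
    }
    if (i == 0 && j > 0) state = 2;
    if (j == 0 && i > 0) state = 1;
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(_["score"] = best, _["moves"] = wrap(moves));
}

// Smith-Waterman local alignment over a precomputed column-score matrix,
// affine gaps as above. Score is never negative. Ties in the optimal cell
// are broken toward the smallest (i, j). Returns score and the 1-based
// aligned intervals [a_start, a_end], [b_start, b_end] (0s when score 0).
// [[Rcpp::export(name = ".sw_dp")]]
List sw_dp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e300;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = 0; X(i, j) = NEG; Y(i, j) = NEG; }
  double best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double prev = std::max(std::max(M(i - 1, j - 1), X(i - 1, j - 1)),
                             Y(i - 1, j - 1));
      M(i, j) = std::max(0.0, prev + S(i - 1, j - 1));
      X(i, j) = std::max(M(i - 1, j) + gap_open, X(i - 1, j) + gap_extend);
      Y(i, j) = std::max(M(i, j - 1) + gap_open, Y(i, j - 1) + gap_extend);
      if (M(i, j) > best + 1e-12) { best = M(i, j); bi = i; bj = j; }
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0);
  // traceback from (bi, bj) until the local path starts
  int i = bi, j = bj, state = 0;
  const double eps = 1e-9;
  while (i > 0 && j > 0) {
    if (state == 0) {
      double target = M(i, j) - S(i - 1, j - 1);
      --i; --j;
      if (target <= eps) break; // path starts at the cell we just left
      if (std::abs(M(i, j) - target) < eps) state = 0;
      else if (std::abs(X(i, j) - target) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      double v = X(i, j); --i;
      state = (std::abs(M(i, j) + gap_open - v) < eps) ? 0 : 1;
    } else {
      double v = Y(i, j); --j;
      state = (std::abs(M(i, j) + gap_open - v) < eps) ? 0 : 2;
    }
  }
  return List::create(_["score"] = best, _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj);
}
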