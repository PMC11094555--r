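#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment over gene positions. The match predicate
// (non-empty label-set intersection) is evaluated in R and passed in as a
// logical matrix; here we only run the dynamic program and the traceback.
//
// Cell recurrence: H[i][j] = max(0, H[i-1][j-1] + s(i,j),
//                                H[i-1][j] + gap, H[i][j-1] + gap)
// Best cell: maximum H, ties resolved to the smallest (i, j) by scan order.
// Traceback prefers diagonal over up (gap in v) over left (gap in u) and
// stops at the first zero cell. Diagonal steps (match or mismatch) are the
// reported aligned pairs, 1-based.
// [[Rcpp::export(name = ".sw_align_core")]]
List sw_align_core(LogicalMatrix match, double matchScore,
                   double mismatchScore, double gapScore) {
  const int n = match.nrow();
  const int m = match.ncol();
  NumericMatrix H(n + 1, m + 1); // zero-initialized
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = match(i - 1, j - 1) ? matchScore : mismatchScore;
      double diag = H(i - 1, j - 1) + s;
      double up = H(i - 1, j) + gapScore;
      double left = H(i, j - 1) + gapScore;
      double h = diag;
      if (up > h) h = up;
      if (left > h) h = left;
      if (h < 0.0) h = 0.0;
      H(i, j) = h;
      if (h > best) { // strict: keeps the smallest (i, j) on ties
        best = h;
        bi = i;
        bj = j;
      }
    }
  }
  std::vector<int> pu, pv;
  const double eps = 1e-9;
  int i = bi, j = bj;
  while (i > 0 && j > 0 && H(i, j) > eps) {
    double s = match(i - 1, j - 1) ? matchScore : mismatchScore;
    if (std::abs(H(i, j) - (H(i - 1, j - 1) + s)) < eps) {
      pu.push_back(i);
      pv.push_back(j);
      --i; --j;
    } else if (std::abs(H(i, j) - (H(i - 1, j) + gapScore)) < eps) {
      --i;
    } else {
      --j;
    }
  }
  const int k = (int)pu.size();
  IntegerMatrix pairs(k, 2);
  for (int t = 0; t < k; ++t) { // collected back-to-front
    pairs(t, 0) = pu[k - 1 - t];
    pairs(t, 1) = pv[k - 1 - t];
  }
  return List::create(_["score"] = best, _["pairs"] = pairs);
}
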