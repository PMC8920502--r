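#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline double eucl(const NumericMatrix& A, int i,
                          const NumericMatrix& B, int j) {
  double s = 0.0;
  for (int k = 0; k < A.ncol(); ++k) {
    double d = A(i, k) - B(j, k);
    s += d * d;
  }
  return std::sqrt(s);
}

// Classic dynamic time warping with unit step pattern (no window, no
// normalization); local cost is the Euclidean distance between multivariate
// samples.  Returns the accumulated cost of the optimal monotone alignment.
// [[Rcpp::export]]
double dtw_cost_cpp(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = inf;
    for (int j = 1; j <= m; ++j) {
      double c = eucl(A, i - 1, B, j - 1);
      double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// All-pairs DTW distance matrix over a list of T_i x d matrices.
// [[Rcpp::export]]
NumericMatrix dtw_matrix_cpp(List seqs) {
  const int n = seqs.size();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix A = seqs[i];
    for (int j = i + 1; j < n; ++j) {
      NumericMatrix B = seqs[j];
      double d = dtw_cost_cpp(A, B);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// Sub-sequence DTW: the short query Q must be matched in full against a
// contiguous window of the series S (free start and end on the series
// axis).  Returns the optimal cost and the 1-based window [start, end] in S.
// [[Rcpp::export]]
List subseq_dtw_cpp(NumericMatrix Q, NumericMatrix S) {
  const int n = Q.nrow(), m = S.nrow();
  const double inf = std::numeric_limits<double>::infinity();
  NumericMatrix D(n, m);
  IntegerMatrix from(n, m); // 0 = start here, 1 = diag, 2 = up, 3 = left
  for (int j = 0; j < m; ++j) {
    D(0, j) = eucl(Q, 0, S, j);
    from(0, j) = 0;
  }
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = eucl(Q, i, S, j);
      double best = inf;
      int arg = 1;
      if (j > 0 && D(i - 1, j - 1) < best) { best = D(i - 1, j - 1); arg = 1; }
      if (D(i - 1, j) < best) { best = D(i - 1, j); arg = 2; }
      if (j > 0 && D(i, j - 1) < best) { best = D(i, j - 1); arg = 3; }
      D(i, j) = c + best;
      from(i, j) = arg;
    }
  }
  int jend = 0;
  for (int j = 1; j < m; ++j) if (D(n - 1, j) < D(n - 1, jend)) jend = j;
  // backtrack for the window start
  int i = n - 1, j = jend;
  while (i > 0 || from(i, j) != 0) {
    int a = from(i, j);
    if (a == 1) { --i; --j; }
    else if (a == 2) { --i; }
    else if (a == 3) { --j; }
    else break;
  }
  return List::create(_["cost"] = D(n - 1, jend),
                      _["start"] = j + 1, _["end"] = jend + 1);
}
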