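#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Best-matching unit per row of X: minimal Euclidean distance to the
// codebook rows, ties broken by the lowest (1-based) linear index.
// [[Rcpp::export]]
IntegerVector bmu_cpp(NumericMatrix X, NumericMatrix codebook) {
  const int n = X.nrow(), m = codebook.nrow(), d = X.ncol();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int arg = 0;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double df = X(i, k) - codebook(j, k);
        s += df * df;
      }
      if (s < best) { best = s; arg = j; }
    }
    out[i] = arg + 1;
  }
  return out;
}

// Online SOM training on a rows x cols grid.  Samples are presented in the
// caller-supplied order each epoch (deterministic); the learning rate
// decays linearly from lr0 to lr1 over epochs.  A neuron is updated when
// its Euclidean grid distance to the BMU is <= radius, with Gaussian
// neighborhood weight exp(-dist^2 / (2 std^2)).
// [[Rcpp::export]]
NumericMatrix som_train_cpp(NumericMatrix X, int gridRows, int gridCols,
                            int epochs, double radius, double stddev,
                            NumericMatrix init, double lr0, double lr1,
                            IntegerVector order) {
  const int n = X.nrow(), d = X.ncol(), m = gridRows * gridCols;
  NumericMatrix W = clone(init);
  // neighbors within grid radius, precomputed with weights
  std::vector< std::vector<int> > nbr(m);
  std::vector< std::vector<double> > nbw(m);
  for (int a = 0; a < m; ++a) {
    int ar = a / gridCols, ac = a % gridCols;
    for (int b = 0; b < m; ++b) {
      int br = b / gridCols, bc = b % gridCols;
      double g2 = (double)((ar - br) * (ar - br) + (ac - bc) * (ac - bc));
      if (std::sqrt(g2) <= radius + 1e-12) {
        nbr[a].push_back(b);
        nbw[a].push_back(std::exp(-g2 / (2.0 * stddev * stddev)));
      }
    }
  }
  for (int e = 0; e < epochs; ++e) {
    double lr = (epochs > 1)
      ? lr0 + (lr1 - lr0) * (double)e / (double)(epochs - 1) : lr0;
    for (int t = 0; t < n; ++t) {
      int i = order[t] - 1;
      // BMU
      double best = std::numeric_limits<double>::infinity();
      int arg = 0;
      for (int j = 0; j < m; ++j) {
        double s = 0.0;
        for (int k = 0; k < d; ++k) {
          double df = X(i, k) - W(j, k);
          s += df * df;
        }
        if (s < best) { best = s; arg = j; }
      }
      const std::vector<int>& nb = nbr[arg];
      const std::vector<double>& nw = nbw[arg];
      for (size_t q = 0; q < nb.size(); ++q) {
        int j = nb[q];
        double a = lr * nw[q];
        for (int k = 0; k < d; ++k)
          W(j, k) += a * (X(i, k) - W(j, k));
      }
    }
  }
  return W;
}
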