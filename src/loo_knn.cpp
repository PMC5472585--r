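// Leave-one-out k-nearest-neighbor predictions with fully deterministic
// tie handling: equal distances prefer the smaller row index, vote ties the
// smaller class index. Distances are squared Euclidean computed blockwise
// from a Gram product so n = 20,000 stays tractable on one core.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector loo_knn_pred_cpp(const arma::mat& X, const IntegerVector& y,
                               const int k, const int n_classes) {
  const int n = X.n_rows;
  if (k < 1) stop("k must be >= 1");
  if (n < k + 1) stop("need at least k + 1 rows");
  arma::vec norms = arma::sum(arma::square(X), 1);
  IntegerVector pred(n);
  const int block = 1024;
  std::vector<double> kd(k);
  std::vector<int> kj(k);
  for (int r0 = 0; r0 < n; r0 += block) {
    const int r1 = std::min(n, r0 + block);
    arma::mat G = X.rows(r0, r1 - 1) * X.t();
    for (int i = r0; i < r1; ++i) {
      const int bi = i - r0;
      int filled = 0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double d2 = norms[i] + norms[j] - 2.0 * G(bi, j);
        const bool insert =
            (filled < k) ||
            (d2 < kd[filled - 1]) ||
            (d2 == kd[filled - 1] && j < kj[filled - 1]);
        if (!insert) continue;
        int p = (filled < k) ? filled++ : k - 1;
        while (p > 0 && (kd[p - 1] > d2 || (kd[p - 1] == d2 && kj[p - 1] > j))) {
          kd[p] = kd[p - 1];
          kj[p] = kj[p - 1];
          --p;
        }
        kd[p] = d2;
        kj[p] = j;
      }
      std::vector<int> votes(n_classes, 0);
      for (int t = 0; t < filled; ++t) votes[y[kj[t]]]++;
      int best = 0;
      for (int c = 1; c < n_classes; ++c)
        if (votes[c] > votes[best]) best = c;
      pred[i] = best;
    }
  }
  return pred;
}
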