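// Inner leave-one-out loop of the CPM component-selection step.
//
// For each left-out row i: center the remaining rows, take the PCA of
// the centered block (thin SVD), regress the behavior score on the
// leading component scores, and predict the left-out row for every
// candidate component count 1..cmax in one cumulative pass (component
// scores are orthogonal, so per-component slopes are independent).
//
// Returns an n x cmax matrix of leave-one-out predictions; column c
// holds the prediction using c components. Candidate counts beyond the
// rank of the training block reuse the full-rank prediction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export(name = ".cv_component_predictions_cpp")]]
arma::mat cv_component_predictions_cpp(const arma::mat &X,
                                       const arma::vec &y, int cmax) {
  const int n = X.n_rows, m = X.n_cols;
  if ((int)y.n_elem != n) Rcpp::stop("length(y) != nrow(X)");
  if (cmax < 1) Rcpp::stop("cmax must be >= 1");
  arma::mat P(n, cmax);

  for (int i = 0; i < n; ++i) {
    arma::uvec keep(n - 1);
    int p = 0;
    for (int j = 0; j < n; ++j) if (j != i) keep[p++] = j;
    arma::mat Xtr = X.rows(keep);
    arma::vec ytr = y.elem(keep);
    arma::rowvec mu = arma::mean(Xtr, 0);
    Xtr.each_row() -= mu;
    const double ybar = arma::mean(ytr);

    arma::mat U, V;
    arma::vec d;
    if (!arma::svd_econ(U, d, V, Xtr))
      Rcpp::stop("SVD failed in inner cross-validation");

    const double tol = (d.n_elem ? d[0] : 0.0) * 1e-10;
    int rank = 0;
    for (arma::uword q = 0; q < d.n_elem; ++q)
      if (d[q] > tol && rank < std::min(n - 2, m)) ++rank; else break;

    arma::rowvec t = (X.row(i) - mu) * V; // left-out component scores
    double pred = ybar;
    for (int c = 1; c <= cmax; ++c) {
      if (c <= rank) {
        // slope of ytr on score column c: scores are centered and
        // orthogonal with squared norm d[c-1]^2
        const double beta =
            arma::dot(U.col(c - 1), ytr) / d[c - 1];
        pred += t[c - 1] * beta;
      }
      P(i, c - 1) = pred;
    }
  }
  return P;
}
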