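// Log-space forward-backward for the linear-chain CRF: negative
// log-likelihood plus exact gradients wrt emissions and transitions.
// tags are 1-based indices from R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::rowvec lse_cols(const arma::mat& M) {
  arma::rowvec mx = arma::max(M, 0);
  return mx + arma::log(arma::sum(arma::exp(M.each_row() - mx), 0));
}

static arma::vec lse_rows(const arma::mat& M) {
  arma::vec mx = arma::max(M, 1);
  return mx + arma::log(arma::sum(arma::exp(M.each_col() - mx), 1));
}

// [[Rcpp::export]]
List crf_grad_cpp(const arma::mat& E, const arma::mat& Tr,
                  const arma::ivec& tags) {
  const int n = E.n_rows;
  const int K = E.n_cols;
  arma::mat alpha(n, K), beta(n, K, arma::fill::zeros);
  alpha.row(0) = E.row(0);
  for (int t = 1; t < n; ++t) {
    arma::mat M = Tr;
    M.each_col() += alpha.row(t - 1).t();
    alpha.row(t) = E.row(t) + lse_cols(M);
  }
  for (int t = n - 2; t >= 0; --t) {
    arma::mat M = Tr;
    M.each_row() += E.row(t + 1) + beta.row(t + 1);
    beta.row(t) = lse_rows(M).t();
  }
  double mx = alpha.row(n - 1).max();
  double logZ = mx + std::log(arma::sum(arma::exp(alpha.row(n - 1) - mx)));

  arma::mat dE = arma::exp(alpha + beta - logZ);
  double score = 0.0;
  for (int t = 0; t < n; ++t) {
    dE(t, tags[t] - 1) -= 1.0;
    score += E(t, tags[t] - 1);
    if (t > 0) score += Tr(tags[t - 1] - 1, tags[t] - 1);
  }
  arma::mat dT(K, K, arma::fill::zeros);
  for (int t = 0; t + 1 < n; ++t) {
    arma::mat M = Tr;
    M.each_col() += alpha.row(t).t();
    M.each_row() += E.row(t + 1) + beta.row(t + 1);
    dT += arma::exp(M - logZ);
    dT(tags[t] - 1, tags[t + 1] - 1) -= 1.0;
  }
  return List::create(_["nll"] = logZ - score, _["dE"] = dE, _["dT"] = dT);
}
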