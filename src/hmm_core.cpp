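// Per-segment HMM recursions. These are the only per-sample loops in the
// package; everything model-related (VB updates, priors, free energy) is in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Scaled forward-backward for one segment.
//
// logB: S x K matrix of (expected) log emission densities.
// A:    K x K transition matrix (already exponentiated, rows need not sum
//       to exactly 1 when built from expected log parameters).
// pi0:  length-K initial weights (same remark).
//
// Returns gamma (S x K), xi_sum (K x K summed two-slice marginals), and
// loglik = log sum over paths of prod pi0 * A * exp(logB), computed with
// per-step scaling. Row maxima of logB are subtracted before
// exponentiating and added back into loglik, so arbitrarily small
// densities do not underflow.
// [[Rcpp::export]]
List fb_segment(const arma::mat& logB, const arma::mat& A,
                const arma::rowvec& pi0) {
  const arma::uword S = logB.n_rows, K = logB.n_cols;
  arma::vec rowmax = arma::max(logB, 1);
  arma::mat B = arma::exp(logB.each_col() - rowmax);

  arma::mat alpha(S, K), beta(S, K);
  arma::vec c(S);

  alpha.row(0) = pi0 % B.row(0);
  c(0) = arma::accu(alpha.row(0));
  if (!(c(0) > 0.0) || !std::isfinite(c(0)))
    stop("forward recursion underflow at t=1");
  alpha.row(0) /= c(0);
  for (arma::uword t = 1; t < S; ++t) {
    alpha.row(t) = (alpha.row(t - 1) * A) % B.row(t);
    c(t) = arma::accu(alpha.row(t));
    if (!(c(t) > 0.0) || !std::isfinite(c(t)))
      stop("forward recursion underflow at t=" + std::to_string(t + 1));
    alpha.row(t) /= c(t);
  }

  beta.row(S - 1).ones();
  for (arma::uword t = S - 1; t-- > 0;) {
    beta.row(t) = ((beta.row(t + 1) % B.row(t + 1)) * A.t()) / c(t + 1);
  }

  arma::mat gamma = alpha % beta;
  gamma.each_col() /= arma::sum(gamma, 1);  // guard tiny drift

  arma::mat xi(K, K, arma::fill::zeros);
  for (arma::uword t = 1; t < S; ++t) {
    arma::mat x = (alpha.row(t - 1).t() * (beta.row(t) % B.row(t))) % A;
    xi += x / c(t);
  }

  double loglik = arma::accu(arma::log(c)) + arma::accu(rowmax);
  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi,
                      _["loglik"] = loglik);
}

// Viterbi decoding for one segment, fully in log space.
// Ties broken toward the lowest state index (strict > when comparing).
// Returns 1-based state indices.
// [[Rcpp::export]]
arma::uvec viterbi_segment(const arma::mat& logB, const arma::mat& logA,
                           const arma::rowvec& logpi) {
  const arma::uword S = logB.n_rows, K = logB.n_cols;
  arma::mat delta(S, K);
  arma::umat psi(S, K, arma::fill::zeros);

  delta.row(0) = logpi + logB.row(0);
  for (arma::uword t = 1; t < S; ++t) {
    for (arma::uword k = 0; k < K; ++k) {
      double best = delta(t - 1, 0) + logA(0, k);
      arma::uword arg = 0;
      for (arma::uword j = 1; j < K; ++j) {
        double v = delta(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logB(t, k);
      psi(t, k) = arg;
    }
  }

  arma::uvec path(S);
  double best = delta(S - 1, 0);
  arma::uword arg = 0;
  for (arma::uword k = 1; k < K; ++k)
    if (delta(S - 1, k) > best) { best = delta(S - 1, k); arg = k; }
  path(S - 1) = arg;
  for (arma::uword t = S - 1; t-- > 0;) path(t) = psi(t + 1, path(t + 1));
  return path + 1;
}
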