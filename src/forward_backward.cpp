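// Scaled forward-backward recursions for an HMM with arbitrary
// (precomputed) log emission densities.  Rabiner-style scaling with an
// additional per-row shift of the emission matrix keeps everything finite
// for sequences up to ~1e5 windows.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// logB: T x Q log emission densities; a: Q x Q transitions; pi: length Q.
// Returns scaled alpha/beta, gamma, the full zeta cube (T-1 x Q x Q),
// per-step log scale factors and the total log-likelihood.
// [[Rcpp::export(name = ".fb_core")]]
Rcpp::List fb_core(const arma::mat& logB, const arma::mat& a,
                   const arma::vec& pi) {
  const uword T = logB.n_rows, Q = logB.n_cols;

  vec m = max(logB, 1);                   // per-window shift
  mat B = exp(logB.each_col() - m);       // shifted emission likelihoods

  mat alpha(T, Q), beta(T, Q);
  vec logc(T);                            // log c_t + m_t

  rowvec v = pi.t() % B.row(0);
  double s = accu(v);
  alpha.row(0) = v / s;
  logc(0) = std::log(s) + m(0);
  for (uword t = 1; t < T; ++t) {
    v = (alpha.row(t - 1) * a) % B.row(t);
    s = accu(v);
    alpha.row(t) = v / s;
    logc(t) = std::log(s) + m(t);
  }

  beta.row(T - 1).ones();
  for (uword t = T - 1; t-- > 0;) {
    // c_{t+1} in shifted units is exp(logc(t+1) - m(t+1))
    double c1 = std::exp(logc(t + 1) - m(t + 1));
    beta.row(t) = ((B.row(t + 1) % beta.row(t + 1)) * a.t()) / c1;
  }

  mat gamma = alpha % beta;
  gamma.each_col() /= sum(gamma, 1);      // guard tiny rounding drift

  cube zeta(Q, Q, T > 1 ? T - 1 : 0);
  for (uword t = 0; t + 1 < T; ++t) {
    double c1 = std::exp(logc(t + 1) - m(t + 1));
    rowvec bb = B.row(t + 1) % beta.row(t + 1);
    mat z = (alpha.row(t).t() * bb) % a / c1;
    z /= accu(z);                         // rows of gamma are normalized
    zeta.slice(t) = z;
  }

  return Rcpp::List::create(
    Rcpp::Named("alpha") = alpha, Rcpp::Named("beta") = beta,
    Rcpp::Named("gamma") = gamma, Rcpp::Named("zeta") = zeta,
    Rcpp::Named("logc") = logc,
    Rcpp::Named("loglik") = accu(logc));
}
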