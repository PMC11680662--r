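// Adaptive one-equation MVAR predictor via a Kalman filter with
// random-walk coefficients. Used by the Granger-causality module: the
// target channel is regressed on lagged copies of all predictor channels;
// the time course of the smoothed one-step prediction error variance is
// returned so that full and reduced models can be compared per timepoint.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// y: T observations; Phi: T x p lagged regressor matrix (row t predicts
// y[t]); c: scalar adaptation constant (coefficient random-walk gain and
// observation-noise tracking); ce: smoothing constant for the reported
// error-variance time course; p0: initial coefficient variance.
// Returns a list with the per-timepoint smoothed squared prediction error
// (ema) and the raw one-step errors (err).
// [[Rcpp::export]]
List cpp_kalman_errors(const arma::vec& y, const arma::mat& Phi,
                       double c, double ce, double p0) {
  const arma::uword T = y.n_elem, p = Phi.n_cols;
  if (Phi.n_rows != T) stop("Phi rows must match length(y)");
  if (!y.is_finite() || !Phi.is_finite()) stop("non-finite signals");
  arma::vec theta(p, arma::fill::zeros);
  arma::mat P = p0 * arma::eye(p, p);
  double R = 1.0, E = 1.0;
  arma::vec err(T), ema(T);
  for (arma::uword t = 0; t < T; ++t) {
    const arma::rowvec phi = Phi.row(t);
    P *= (1.0 + c);                         // random-walk state inflation
    const double e = y[t] - arma::dot(phi, theta);
    const arma::vec Pphi = P * phi.t();
    const double S = arma::dot(phi, Pphi) + R;
    const arma::vec K = Pphi / S;
    theta += K * e;
    P -= K * Pphi.t();
    P = 0.5 * (P + P.t());                  // keep symmetric
    R = (1.0 - c) * R + c * e * e;
    E = (1.0 - ce) * E + ce * e * e;
    err[t] = e;
    ema[t] = E;
  }
  return List::create(_["ema"] = ema, _["err"] = err);
}
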