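// Compact linear soft-margin SVM (C-SVC, C = 1) solved by SMO on the dual
// with maximal-violating-pair working-set selection. Built for the decoding
// inner loop: hundreds of thousands of tiny problems (<= ~16 training bins,
// 8 features), one per timepoint and bin assignment, where per-call overhead
// of a general-purpose SVM wrapper dominates. Deterministic: fixed selection
// rule, ties at the decision boundary go to class +1 (class A).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct SvmModel {
  std::vector<double> w;
  double b;
};

// X: n x d row-major, y in {+1,-1}. Returns primal weights and bias.
SvmModel solve_linear_svm(const std::vector<double>& X,
                          const std::vector<double>& y,
                          int n, int d, double C = 1.0,
                          double eps = 1e-8, int max_iter = 10000) {
  std::vector<double> K(static_cast<size_t>(n) * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j <= i; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k)
        s += X[i * d + k] * X[j * d + k];
      K[i * n + j] = K[j * n + i] = s;
    }
  std::vector<double> alpha(n, 0.0), G(n, -1.0);

  double m = 0.0, M = 0.0;
  for (int it = 0; it < max_iter; ++it) {
    int ii = -1, jj = -1;
    m = -HUGE_VAL; M = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (up && v > m) { m = v; ii = t; }
      if (lo && v < M) { M = v; jj = t; }
    }
    if (ii < 0 || jj < 0 || m - M < eps) break;

    double quad = K[ii * n + ii] + K[jj * n + jj] - 2.0 * K[ii * n + jj];
    if (quad <= 1e-12) quad = 1e-12;
    double t_step = (m - M) / quad;  // unconstrained optimum along the pair
    // Box constraints for a_i + y_i t and a_j - y_j t in [0, C].
    double lo_t = -HUGE_VAL, hi_t = HUGE_VAL;
    if (y[ii] > 0) { lo_t = std::max(lo_t, -alpha[ii]); hi_t = std::min(hi_t, C - alpha[ii]); }
    else           { lo_t = std::max(lo_t, alpha[ii] - C); hi_t = std::min(hi_t, alpha[ii]); }
    if (y[jj] > 0) { lo_t = std::max(lo_t, alpha[jj] - C); hi_t = std::min(hi_t, alpha[jj]); }
    else           { lo_t = std::max(lo_t, -alpha[jj]); hi_t = std::min(hi_t, C - alpha[jj]); }
    if (t_step < lo_t) t_step = lo_t;
    if (t_step > hi_t) t_step = hi_t;
    if (t_step == 0.0) break;

    alpha[ii] += y[ii] * t_step;
    alpha[jj] -= y[jj] * t_step;
    for (int k = 0; k < n; ++k)
      G[k] += y[k] * t_step * (K[k * n + ii] - K[k * n + jj]);
  }

  SvmModel mod;
  mod.w.assign(d, 0.0);
  for (int i = 0; i < n; ++i) {
    if (alpha[i] != 0.0)
      for (int k = 0; k < d; ++k)
        mod.w[k] += alpha[i] * y[i] * X[i * d + k];
  }
  // Bias from the KKT gap midpoint; equals y_i - w'x_i on free SVs.
  double bm = -HUGE_VAL, bM = HUGE_VAL;
  for (int t = 0; t < n; ++t) {
    double v = -y[t] * G[t];
    bool up = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
    bool lo = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
    if (up && v > bm) bm = v;
    if (lo && v < bM) bM = v;
  }
  mod.b = (bm + bM) / 2.0;
  return mod;
}

}  // namespace

// [[Rcpp::export]]
List cpp_svm_fit(NumericMatrix X, NumericVector y) {
  int n = X.nrow(), d = X.ncol();
  std::vector<double> Xr(static_cast<size_t>(n) * d), yv(n);
  for (int i = 0; i < n; ++i) {
    yv[i] = y[i];
    for (int k = 0; k < d; ++k) Xr[i * d + k] = X(i, k);
  }
  SvmModel m = solve_linear_svm(Xr, yv, n, d);
  return List::create(_["w"] = NumericVector(m.w.begin(), m.w.end()),
                      _["b"] = m.b);
}

// trainA/trainB/testA/testB: arrays (bins x d x T), column-major R layout.
// Returns per-timepoint transfer accuracy: fraction of test bins classified
// as their own class (A = +1, B = -1); decision ties count as class A.
// [[Rcpp::export]]
NumericVector cpp_pair_accuracy(NumericVector trainA, NumericVector trainB,
                                NumericVector testA, NumericVector testB) {
  IntegerVector dA = trainA.attr("dim"), dB = trainB.attr("dim");
  IntegerVector eA = testA.attr("dim"), eB = testB.attr("dim");
  int naTr = dA[0], d = dA[1], T = dA[2];
  int nbTr = dB[0], naTe = eA[0], nbTe = eB[0];
  if (dB[1] != d || eA[1] != d || eB[1] != d || dB[2] != T ||
      eA[2] != T || eB[2] != T)
    stop("dimension mismatch between train/test arrays");
  int n = naTr + nbTr;
  NumericVector acc(T);
  std::vector<double> X(static_cast<size_t>(n) * d), y(n);
  for (int i = 0; i < naTr; ++i) y[i] = 1.0;
  for (int i = naTr; i < n; ++i) y[i] = -1.0;

  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < naTr; ++i)
      for (int k = 0; k < d; ++k)
        X[i * d + k] = trainA[i + naTr * k + naTr * d * t];
    for (int i = 0; i < nbTr; ++i)
      for (int k = 0; k < d; ++k)
        X[(naTr + i) * d + k] = trainB[i + nbTr * k + nbTr * d * t];
    SvmModel m = solve_linear_svm(X, y, n, d);
    int correct = 0;
    for (int i = 0; i < naTe; ++i) {
      double f = m.b;
      for (int k = 0; k < d; ++k)
        f += m.w[k] * testA[i + naTe * k + naTe * d * t];
      if (f >= 0) ++correct;
    }
    for (int i = 0; i < nbTe; ++i) {
      double f = m.b;
      for (int k = 0; k < d; ++k)
        f += m.w[k] * testB[i + nbTe * k + nbTe * d * t];
      if (f < 0) ++correct;
    }
    acc[t] = static_cast<double>(correct) / (naTe + nbTe);
  }
  return acc;
}
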