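// Two-class C-SVC dual solver: SMO with maximal-violating-pair working
// set selection (the classical decomposition scheme for kernel SVMs).
// Problem sizes here are tiny (tens of samples), so the full kernel
// matrix is precomputed by the caller and passed in.
//
//   min_a  0.5 a' Q a - e' a,  0 <= a_i <= C,  y' a = 0,
//   Q_ij = y_i y_j K_ij,  y_i in {-1, +1}.

#include <Rcpp.h>
using namespace Rcpp;

static const double TAU = 1e-12;

// [[Rcpp::export]]
List svm_smo_fit(NumericMatrix K, IntegerVector y, double C,
                 double eps = 1e-3, int max_iter = 100000) {
  int n = K.nrow();
  std::vector<double> alpha(n, 0.0), grad(n, -1.0);
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // maximal violating pair
    int i = -1, j = -1;
    double gmax = -1e300, gmin = 1e300;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      bool lo = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      double v = -y[t] * grad[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (lo && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) break;

    double ai_old = alpha[i], aj_old = alpha[j];
    if (y[i] != y[j]) {
      double quad = K(i, i) + K(j, j) - 2 * K(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (-grad[i] - grad[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      double quad = K(i, i) + K(j, j) - 2 * K(i, j);
      if (quad <= 0) quad = TAU;
      double delta = (grad[i] - grad[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }
    double di = y[i] * (alpha[i] - ai_old), dj = y[j] * (alpha[j] - aj_old);
    for (int t = 0; t < n; ++t)
      grad[t] += y[t] * (K(t, i) * di + K(t, j) * dj);
  }

  // intercept: average of -y g over free vectors, else midpoint of bounds
  double bsum = 0; int nfree = 0;
  double ub = 1e300, lb = -1e300;
  for (int t = 0; t < n; ++t) {
    double v = -y[t] * grad[t];
    bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
    bool lo = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
    if (alpha[t] > 0 && alpha[t] < C) { bsum += v; ++nfree; }
    if (up && v < ub) ub = v;
    if (lo && v > lb) lb = v;
  }
  double b = nfree > 0 ? bsum / nfree : (ub + lb) / 2;

  // dual objective 0.5 a'Qa - e'a = 0.5 * sum a_t (grad_t - 1)
  double obj = 0;
  for (int t = 0; t < n; ++t) obj += alpha[t] * (grad[t] - 1.0);
  obj *= 0.5;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iter"] = iter, _["objective"] = obj);
}
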