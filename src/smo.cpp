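#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the L1-loss soft-margin SVM dual:
//
//   min_a  0.5 * a' Q a - e' a   s.t.  0 <= a_i <= C,  y' a = 0
//
// with Q_ij = y_i y_j K_ij. Working-set selection is the maximal violating
// pair; convergence is declared when the KKT gap m(a) - M(a) drops below
// `tol`. Only the (small) n x n Gram matrix is passed in, so permutation
// refits reuse one kernel evaluation.

// [[Rcpp::export(name = ".smo_solve")]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double tol = 1e-6, int max_iter = 10000000) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("Gram matrix must be square");
  if (y.size() != n) stop("label length must match Gram matrix");

  std::vector<double> alpha(n, 0.0);
  // grad_i = (Q a)_i - 1; starts at -1 with a = 0
  std::vector<double> grad(n, -1.0);

  int iter = 0;
  double m = 0.0, M = 0.0;
  for (iter = 0; iter < max_iter; ++iter) {
    // i: argmax over I_up of -y_t grad_t ; j: argmin over I_low
    int i = -1, j = -1;
    m = -std::numeric_limits<double>::infinity();
    M = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * grad[t];
      bool in_up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      bool in_low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (in_up && v > m) { m = v; i = t; }
      if (in_low && v < M) { M = v; j = t; }
    }
    if (i < 0 || j < 0 || m - M < tol) break;

    // Restrict to the pair (i, j): move a_i by y_i * d, a_j by -y_j * d,
    // which keeps y' a fixed. Curvature along the direction:
    double a2 = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (a2 <= 0) a2 = 1e-12;
    double d = (m - M) / a2;

    // Box clipping for both coordinates
    double di_max = (y[i] > 0) ? (C - alpha[i]) : alpha[i];
    double dj_max = (y[j] > 0) ? alpha[j] : (C - alpha[j]);
    if (d > di_max) d = di_max;
    if (d > dj_max) d = dj_max;

    double dai = y[i] * d;
    double daj = -y[j] * d;
    alpha[i] += dai;
    alpha[j] += daj;

    for (int t = 0; t < n; ++t)
      grad[t] += y[t] * (y[i] * K(i, t) * dai + y[j] * K(j, t) * daj);
  }

  // Bias from free support vectors (KKT stationarity); fall back to the
  // midpoint of the feasible interval when no alpha is strictly interior.
  double bsum = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-8 * C && alpha[t] < C * (1 - 1e-8)) {
      bsum += -y[t] * grad[t];
      ++nfree;
    }
  }
  double b = (nfree > 0) ? bsum / nfree : (m + M) / 2.0;

  // Dual objective: sum(a) - 0.5 a' Q a = sum(a) + 0.5 * sum(a * (grad - 1))
  // since grad = Q a - 1  =>  a' Q a = a' grad + sum(a).
  double asum = 0.0, aQa = 0.0;
  for (int t = 0; t < n; ++t) {
    asum += alpha[t];
    aQa += alpha[t] * (grad[t] + 1.0);
  }
  double obj = asum - 0.5 * aQa;

  return List::create(
    _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
    _["b"] = b,
    _["objective"] = obj,
    _["iterations"] = iter,
    _["kkt_gap"] = m - M,
    _["converged"] = (m - M < tol));
}
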