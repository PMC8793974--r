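#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Sequential minimal optimization for the soft-margin SVM dual
//
//   min_a  1/2 a' Q a - e' a,   Q_ij = y_i y_j K_ij,
//   s.t.   0 <= a_i <= C,  sum_i a_i y_i = 0,
//
// with maximal-violating-pair working-set selection. The gradient
// G = Q a - e is maintained incrementally; the stopping rule is the
// standard duality gap m - M <= tol on the projected gradient.
//
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, NumericVector y, double C,
               double tol = 1e-8, int max_iter = 500000) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("Gram matrix must be square.");
  if (y.size() != n) stop("Label length must match the Gram matrix.");
  if (C <= 0) stop("Cost must be positive.");

  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  const double TAU = 1e-12;
  const double INF = std::numeric_limits<double>::infinity();
  int it = 0;
  double m = -INF, M = INF;

  for (it = 0; it < max_iter; ++it) {
    m = -INF; M = INF;
    int i_up = -1, i_low = -1;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up  = (y[t] > 0) ? (alpha[t] < C) : (alpha[t] > 0);
      const bool low = (y[t] > 0) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > m) { m = v; i_up = t; }
      if (low && v < M) { M = v; i_low = t; }
    }
    if (i_up < 0 || i_low < 0 || m - M <= tol) break;

    const int i = i_up, j = i_low;
    double quad = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (quad < TAU) quad = TAU;
    double step = (m - M) / quad;
    // keep both multipliers inside [0, C]
    const double cap_i = (y[i] > 0) ? (C - alpha[i]) : alpha[i];
    const double cap_j = (y[j] > 0) ? alpha[j] : (C - alpha[j]);
    const double cap = std::min(cap_i, cap_j);
    if (step > cap) step = cap;
    if (step <= 0) break;  // blocked at the box: no further progress possible

    alpha[i] += y[i] * step;
    alpha[j] -= y[j] * step;
    for (int t = 0; t < n; ++t) {
      G[t] += step * y[t] * (K(t, i) - K(t, j));
    }
  }

  // bias from the KKT conditions: b = -y_i G_i on unbounded support vectors,
  // midpoint of the violating-pair bounds when none are strictly inside
  const double eps_sv = 1e-8 * C;
  double b_sum = 0.0; int b_cnt = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > eps_sv && alpha[t] < C - eps_sv) {
      b_sum += -y[t] * G[t];
      ++b_cnt;
    }
  }
  double bias;
  if (b_cnt > 0) {
    bias = b_sum / b_cnt;
  } else if (std::isfinite(m) && std::isfinite(M)) {
    bias = (m + M) / 2.0;
  } else {
    bias = 0.0;
  }

  // maximized dual objective W(a) = e'a - 1/2 a' Q a = -1/2 sum a_i (G_i - 1)
  double obj = 0.0;
  for (int t = 0; t < n; ++t) obj += alpha[t] * (G[t] - 1.0);
  obj = -0.5 * obj;

  double eq = 0.0;
  for (int t = 0; t < n; ++t) eq += alpha[t] * y[t];

  return List::create(
    _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
    _["bias"] = bias,
    _["objective"] = obj,
    _["iterations"] = it,
    _["kkt_gap"] = (std::isfinite(m) && std::isfinite(M)) ? (m - M) : 0.0,
    _["eq_residual"] = eq,
    _["converged"] = (it < max_iter)
  );
}
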