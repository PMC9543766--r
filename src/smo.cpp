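#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// SMO solver for the epsilon-insensitive SVR dual.
//
// The dual is written as a minimization over 2n box-constrained variables
// beta = (alpha_star, alpha), with signs z = (+1,...,+1, -1,...,-1):
//
//   min  1/2 theta' K theta + eps * sum(beta) - sum_t z_t y_{i(t)} beta_t
//   s.t. sum_t z_t beta_t = 0,   0 <= beta_t <= C,
//
// where theta_i = alpha_star_i - alpha_i.  Each iteration picks the
// maximal-KKT-violating pair (one index from the "up" set, one from the
// "low" set) and solves the two-variable subproblem analytically.  This is
// the classical working-set rule; convergence is declared when the
// violation gap m - M drops to the tolerance.
//
// [[Rcpp::export]]
List smo_solve_cpp(NumericMatrix K, NumericVector y, double C, double eps,
                   double tol, double max_iter) {
  const int n = K.nrow();
  const int N = 2 * n;
  std::vector<double> beta(N, 0.0), G(N);

  // gradient at beta = 0
  for (int t = 0; t < N; ++t) {
    const int i = t % n;
    const double z = (t < n) ? 1.0 : -1.0;
    G[t] = eps - z * y[i];
  }

  const double imax = max_iter;
  double iter = 0.0, gap = R_PosInf;
  bool converged = false;

  while (iter < imax) {
    // maximal violating pair over -z_t * G_t
    int ti = -1, tj = -1;
    double m = R_NegInf, M = R_PosInf;
    for (int t = 0; t < N; ++t) {
      const double z = (t < n) ? 1.0 : -1.0;
      const double v = -z * G[t];
      const bool in_up = (z > 0.0) ? (beta[t] < C) : (beta[t] > 0.0);
      const bool in_low = (z > 0.0) ? (beta[t] > 0.0) : (beta[t] < C);
      if (in_up && v > m) { m = v; ti = t; }
      if (in_low && v < M) { M = v; tj = t; }
    }
    gap = m - M;
    if (ti < 0 || tj < 0 || !(gap > tol)) { converged = (gap <= tol); break; }

    const int i = ti % n, j = tj % n;
    const double zi = (ti < n) ? 1.0 : -1.0;
    const double zj = (tj < n) ? 1.0 : -1.0;

    // step t along (d_beta_i, d_beta_j) = (zi * t, -zj * t)
    const double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    double step = (eta > 1e-12) ? gap / eta : R_PosInf;
    const double cap_i = (zi > 0.0) ? (C - beta[ti]) : beta[ti];
    const double cap_j = (zj > 0.0) ? beta[tj] : (C - beta[tj]);
    if (step > cap_i) step = cap_i;
    if (step > cap_j) step = cap_j;
    if (!(step > 0.0)) { converged = true; break; }  // numerically stuck at optimum

    beta[ti] += zi * step;
    beta[tj] -= zj * step;
    // snap to the box so boundary membership tests stay exact
    if (beta[ti] < 0.0) beta[ti] = 0.0; else if (beta[ti] > C) beta[ti] = C;
    if (beta[tj] < 0.0) beta[tj] = 0.0; else if (beta[tj] > C) beta[tj] = C;

    for (int t = 0; t < N; ++t) {
      const double z = (t < n) ? 1.0 : -1.0;
      const int r = t % n;
      G[t] += z * step * (K(r, i) - K(r, j));
    }
    iter += 1.0;
  }

  NumericVector theta(n);
  for (int i = 0; i < n; ++i) theta[i] = beta[i] - beta[n + i];

  return List::create(_["theta"] = theta,
                      _["iterations"] = iter,
                      _["gap"] = gap,
                      _["converged"] = converged);
}
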