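# Independent quadratic-programming oracle for the SVR dual, built on
# kernlab's interior-point solver.  Solves the dual directly in the 2n
# nonnegative variables (alpha_star, alpha) and returns theta = a* - a.
qp_oracle_theta <- function(K, y, C, eps) {
  n <- length(y)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-10, 2 * n)
  cc <- c(eps - y, eps + y)
  A <- matrix(c(rep(1, n), rep(-1, n)), nrow = 1)
  sol <- kernlab::ipop(cc, H, A, 0, rep(0, 2 * n), rep(C, 2 * n), 0,
                       sigf = 9, maxiter = 200)
  u <- kernlab::primal(sol)
  u[1:n] - u[(n + 1):(2 * n)]
}

# dual objective of a coefficient vector under the minimal-norm
# decomposition (independent of the package's internal computation)
oracle_dual_objective <- function(theta, y, K, eps) {
  sum(y * theta) - eps * sum(abs(theta)) -
    0.5 * drop(t(theta) %*% K %*% theta)
}

# random small SVR problems cycling through the kernel menu
random_svr_problem <- function(r) {
  n <- sample(5:20, 1)
  d <- sample(1:4, 1)
  X <- matrix(stats::rnorm(n * d), n, d)
  y <- stats::rnorm(n, sd = 2)
  kernel <- switch(1 + r %% 5,
                   kernel_rbf(1 / d),
                   kernel_poly(1, 2L),
                   kernel_linear(),
                   kernel_sum_mixture(1 / d, 1, 2L, 0.8),
                   kernel_product_mixture(1 / d, 1, 2L))
  list(X = X, y = y, kernel = kernel,
       C = stats::runif(1, 0.5, 10), eps = stats::runif(1, 0.02, 0.3))
}
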