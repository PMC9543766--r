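tight <- svr_control(kkt_tol = 1e-10, check_kernel = FALSE)

test_that("the one-dimensional hand fixture is solved exactly", {
  # points (0, 0) and (1, 1), linear kernel, eps = 0.1, C = 10: the
  # flattest feasible function is f(x) = 0.8 x + 0.1
  fit <- svr_fit(matrix(c(0, 1)), c(0, 1), kernel_linear(), C = 10,
                 epsilon = 0.1, control = tight)
  expect_equal(fit$theta, c(-0.8, 0.8), tolerance = 1e-9)
  expect_equal(fit$bias, 0.1, tolerance = 1e-9)
  expect_equal(fit$diagnostics$dual_objective, 0.32, tolerance = 1e-9)
  expect_equal(predict(fit, 0.5), 0.5, tolerance = 1e-9)
  expect_equal(sort(fit$support), c(1L, 2L))
  # minimal-norm decomposition: multipliers complementary and in the box
  expect_true(all(fit$alpha * fit$alpha_star == 0))
  expect_true(all(fit$alpha >= 0 & fit$alpha <= 10))
  expect_true(all(fit$alpha_star >= 0 & fit$alpha_star <= 10))
})

test_that("constant targets give the zero-coefficient solution", {
  set.seed(5)
  X <- matrix(rnorm(16), 8, 2)
  for (k in list(kernel_rbf(1), kernel_product_mixture(0.5, 1, 2L))) {
    fit <- svr_fit(X, rep(3.2, 8), k, C = 2, epsilon = 0.1, control = tight)
    expect_equal(fit$theta, rep(0, 8))
    expect_equal(fit$bias, 3.2, tolerance = 1e-9)
    expect_true(all(abs(predict(fit, X) - 3.2) <= 0.1 + 1e-12))
    expect_equal(dual_objective(fit), 0)
  }
})

test_that("SMO matches an independent QP solver on random problems", {
  set.seed(17)
  for (r in 1:12) {
    pb <- random_svr_problem(r)
    K <- kernel_matrix(pb$kernel, pb$X)
    fit <- svr_fit(pb$X, pb$y, pb$kernel, pb$C, pb$eps,
                   control = svr_control(kkt_tol = 1e-8,
                                         check_kernel = FALSE))
    theta0 <- qp_oracle_theta(K, pb$y, pb$C, pb$eps)
    gap <- abs(oracle_dual_objective(fit$theta, pb$y, K, pb$eps) -
                 oracle_dual_objective(theta0, pb$y, K, pb$eps))
    expect_lt(gap, 1e-6)
    # feasibility of the returned model
    expect_true(all(abs(fit$theta) <= pb$C + 1e-9))
    expect_lt(abs(sum(fit$theta)), 1e-8)
    # the bias agrees with the oracle solution's free-point bias; the
    # interior-point oracle itself is only accurate to ~1e-4 here, so the
    # comparison is looser than the objective check above
    free <- which(abs(theta0) > 1e-6 & abs(theta0) < pb$C - 1e-6)
    if (length(free) > 0) {
      E <- pb$y - drop(K %*% theta0)
      expect_equal(fit$bias,
                   mean(E[free] - sign(theta0[free]) * pb$eps),
                   tolerance = 5e-3)
    }
  }
})

test_that("radial fits agree with e1071's epsilon-regression", {
  set.seed(23)
  X <- matrix(rnorm(60), 20, 3)
  y <- X[, 1]^2 + rnorm(20, sd = 0.2)
  gamma <- 0.5; C <- 4; eps <- 0.1
  fit <- svr_fit(X, y, kernel_rbf(gamma), C, eps,
                 control = svr_control(kkt_tol = 1e-8, check_kernel = FALSE))
  ref <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                    gamma = gamma, cost = C, epsilon = eps, scale = FALSE,
                    tolerance = 1e-6)
  Xnew <- matrix(rnorm(30), 10, 3)
  expect_equal(predict(fit, Xnew),
               unname(predict(ref, Xnew)), tolerance = 1e-3)
})

test_that("converged models satisfy the tube and KKT conditions", {
  set.seed(31)
  for (r in 1:6) {
    pb <- random_svr_problem(r)
    fit <- svr_fit(pb$X, pb$y, pb$kernel, pb$C, pb$eps,
                   control = svr_control(kkt_tol = 1e-6,
                                         check_kernel = FALSE))
    expect_lte(kkt_violation(fit), 1e-4)
    resid <- pb$y - fit$fitted
    inactive <- abs(fit$theta) <= 1e-8 * pb$C
    if (any(inactive))
      expect_true(all(abs(resid[inactive]) <= pb$eps + 1e-4))
    # slack decomposition recomputed from residuals
    expect_equal(fit$diagnostics$slack, pmax(0, resid - pb$eps))
    expect_equal(fit$diagnostics$slack_star, pmax(0, -resid - pb$eps))
  }
})

test_that("kkt_violation flags perturbed and degenerate coefficients", {
  fit <- svr_fit(matrix(c(0, 1)), c(0, 1), kernel_linear(), C = 10,
                 epsilon = 0.1, control = tight)
  expect_lte(kkt_violation(fit), 1e-9)
  # equality constraint broken by 0.1
  expect_gte(kkt_violation(fit, theta = c(-0.8, 0.9), bias = 0.1), 0.1 - 1e-9)
  # all-zero coefficients: the point at x = 1 lies outside any feasible tube
  expect_gt(kkt_violation(fit, theta = c(0, 0)), 0.1)
})

test_that("predictions depend only on the support vectors", {
  set.seed(41)
  X <- matrix(rnorm(40), 20, 2)
  y <- sin(X[, 1]) + rnorm(20, sd = 0.05)
  fit <- svr_fit(X, y, kernel_rbf(0.8), C = 5, epsilon = 0.2,
                 control = svr_control(kkt_tol = 1e-8, check_kernel = FALSE))
  expect_lt(length(fit$support), 20L)  # eps-tube induces sparsity here
  refit <- svr_fit(X[fit$support, ], y[fit$support], kernel_rbf(0.8),
                   C = 5, epsilon = 0.2,
                   control = svr_control(kkt_tol = 1e-8,
                                         check_kernel = FALSE))
  Xnew <- matrix(rnorm(20), 10, 2)
  expect_equal(predict(refit, Xnew), predict(fit, Xnew), tolerance = 1e-4)
})

test_that("training loss is non-increasing in C and fits are deterministic", {
  set.seed(53)
  X <- matrix(rnorm(30), 15, 2)
  y <- X[, 1] + 0.5 * X[, 2]^2 + rnorm(15, sd = 0.3)
  losses <- vapply(c(0.1, 1, 10, 100), function(C) {
    fit <- svr_fit(X, y, kernel_rbf(1), C = C, epsilon = 0.1,
                   control = svr_control(kkt_tol = 1e-8,
                                         check_kernel = FALSE))
    sum(fit$diagnostics$slack + fit$diagnostics$slack_star)
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-6))
  f1 <- svr_fit(X, y, kernel_rbf(1), 5, 0.1, control = tight)
  f2 <- svr_fit(X, y, kernel_rbf(1), 5, 0.1, control = tight)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$bias, f2$bias)
})

test_that("degenerate inputs are rejected or reported", {
  X <- matrix(c(0, 1)); y <- c(0, 1)
  expect_error(svr_fit(X, y, kernel_linear(), C = -1), "'C'")
  expect_error(svr_fit(X, y, kernel_linear(), epsilon = -0.1), "'epsilon'")
  expect_error(svr_fit(X, c(0, NA), kernel_linear()), "finite")
  expect_error(svr_fit(X, y, kernel_rbf(1, negate = FALSE), C = 1,
                       epsilon = 0), "admissible")
  err <- tryCatch(
    svr_fit(matrix(rnorm(40)), rnorm(40), kernel_rbf(1), C = 100,
            epsilon = 0,
            control = svr_control(kkt_tol = 1e-12, max_iter = 3,
                                  check_kernel = FALSE)),
    error = identity)
  expect_s3_class(err, "svr_convergence_error")
  expect_true(is.list(err$diagnostics))
  expect_error(predict(svr_fit(X, y, kernel_linear(), C = 1,
                               epsilon = 0.1, control = tight),
                       matrix(1, 1, 3)), "dimension")
})

test_that("epsilon = 0 degenerates the tube but still solves", {
  set.seed(61)
  X <- matrix(rnorm(20), 10, 2)
  y <- X[, 1] + rnorm(10, sd = 0.1)
  fit <- svr_fit(X, y, kernel_rbf(1), C = 10, epsilon = 0,
                 control = svr_control(kkt_tol = 1e-6, check_kernel = FALSE))
  K <- kernel_matrix(kernel_rbf(1), X)
  theta0 <- qp_oracle_theta(K, y, 10, 0)
  expect_lt(abs(oracle_dual_objective(fit$theta, y, K, 0) -
                  oracle_dual_objective(theta0, y, K, 0)), 1e-5)
  expect_gt(length(fit$support), 5L)   # nearly all points become support
})
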