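#' Solver settings for the SMO dual solver
#'
#' @param kkt_tol convergence tolerance on the maximal KKT violation gap of
#'   the working-set selection rule.  The default (1e-3) matches common SMO
#'   practice; tighten it when comparing against an exact quadratic-program
#'   solution.
#' @param max_iter iteration cap; defaults to `1e5 * n` when `NULL`.
#' @param check_kernel logical; verify empirical positive semi-definiteness
#'   of the training Gram matrix before solving.
#' @param seed optional integer; retained for interface stability.  The
#'   maximal-violating-pair rule is deterministic, so the seed currently has
#'   no effect on the solution path.
#' @return a list of class `svr_control`.
#' @export
svr_control <- function(kkt_tol = 1e-3, max_iter = NULL, check_kernel = TRUE,
                        seed = NULL) {
  stopifnot(is.numeric(kkt_tol), kkt_tol > 0)
  structure(list(kkt_tol = kkt_tol, max_iter = max_iter,
                 check_kernel = isTRUE(check_kernel), seed = seed),
            class = "svr_control")
}

#' Fit an epsilon-insensitive support vector regression
#'
#' Solves the SVR dual by sequential minimal optimization (SMO): the flat
#' function `f(x) = sum_i theta_i K(x_i, x) + b` is found by maximizing
#' `sum_i y_i theta_i - eps * sum_i |theta_i| - 1/2 theta' K theta` subject
#' to `sum_i theta_i = 0` and `-C <= theta_i <= C`, where
#' `theta_i = alpha_star_i - alpha_i` combines the two nonnegative dual
#' multipliers of each observation.  Observations with `theta_i != 0` are
#' the support vectors; residuals no larger than `epsilon` incur no loss.
#'
#' @param X numeric feature matrix (observations in rows).
#' @param y numeric response vector.
#' @param kernel a [kernel_spec][kernel_rbf].
#' @param C positive box constraint bounding the dual coefficients; larger
#'   values penalize points outside the epsilon-tube more heavily.
#' @param epsilon nonnegative half-width of the insensitivity tube, in
#'   response units.  `epsilon = 0` is allowed; the tube degenerates and
#'   most points become support vectors.
#' @param control an [svr_control()] settings block.
#' @return an object of class `svr_model` with components `theta`, `alpha`,
#'   `alpha_star` (the minimal-norm decomposition of `theta`), `bias`,
#'   `support`, `kernel`, the training data, and `diagnostics`
#'   (dual objective, iterations, maximal KKT violation, slacks).
#' @examples
#' X <- matrix(c(0, 1), ncol = 1)
#' fit <- svr_fit(X, c(0, 1), kernel_linear(), C = 10, epsilon = 0.1)
#' fit$theta          # c(-0.8, 0.8)
#' predict(fit, 0.5)  # 0.5
#' @export
svr_fit <- function(X, y, kernel, C = 1, epsilon = 0.1,
                    control = svr_control()) {
  X <- as_points(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("'X' and 'y' sizes disagree", call. = FALSE)
  if (n < 1L) stop("need at least one observation", call. = FALSE)
  if (!is.numeric(C) || C <= 0) stop("'C' must be positive", call. = FALSE)
  if (!is.numeric(epsilon) || epsilon < 0)
    stop("'epsilon' must be nonnegative", call. = FALSE)
  if (anyNA(y) || any(!is.finite(y)))
    stop("'y' must be finite", call. = FALSE)
  stopifnot(inherits(kernel, "kernel_spec"), inherits(control, "svr_control"))

  K <- kernel_matrix(kernel, X)
  if (control$check_kernel && n >= 2L) {
    adm <- check_admissible(kernel, X)
    if (!adm$pass)
      stop(sprintf(paste0("kernel is not admissible on the training set ",
                          "(min Gram eigenvalue %.3e)"), adm$min_eigenvalue),
           call. = FALSE)
  }

  max_iter <- if (is.null(control$max_iter)) 1e5 * n else control$max_iter
  sol <- smo_solve_cpp(K, y, C, epsilon, control$kkt_tol, max_iter)
  if (!isTRUE(sol$converged)) {
    cond <- structure(class = c("svr_convergence_error", "error", "condition"),
                      list(message = sprintf(
                        paste0("SMO did not converge in %.0f iterations ",
                               "(KKT gap %.3e > tol %.3e)"),
                        sol$iterations, sol$gap, control$kkt_tol),
                        call = sys.call(-1),
                        diagnostics = sol))
    stop(cond)
  }

  theta <- as.numeric(sol$theta)
  alpha_star <- pmax(theta, 0)        # minimal-norm decomposition
  alpha <- pmax(-theta, 0)
  sv_tol <- 1e-8 * C
  support <- which(abs(theta) > sv_tol)

  bias <- compute_bias(theta, y, K, C, epsilon, sv_tol = sv_tol)
  fitted <- drop(K %*% theta) + bias
  resid <- y - fitted
  slack <- pmax(0, resid - epsilon)
  slack_star <- pmax(0, -resid - epsilon)

  model <- structure(list(
    theta = theta, alpha = alpha, alpha_star = alpha_star, bias = bias,
    support = support, kernel = kernel,
    X = X, y = y, C = C, epsilon = epsilon,
    fitted = fitted,
    diagnostics = list(
      dual_objective = dual_objective_raw(theta, y, K, epsilon),
      iterations = sol$iterations,
      kkt_gap = sol$gap,
      slack = slack, slack_star = slack_star)),
    class = "svr_model")
  model$diagnostics$max_kkt_violation <- kkt_violation(model)
  model
}

#' @export
print.svr_model <- function(x, ...) {
  cat("Epsilon-insensitive SVR\n")
  cat("  kernel:  ", format_kernel_spec(x$kernel), "\n", sep = "")
  cat(sprintf("  n = %d, C = %g, epsilon = %g\n", length(x$y), x$C, x$epsilon))
  cat(sprintf("  support vectors: %d of %d\n", length(x$support), length(x$y)))
  cat(sprintf("  dual objective: %.6g  (max KKT violation %.2e)\n",
              x$diagnostics$dual_objective, x$diagnostics$max_kkt_violation))
  invisible(x)
}

#' Predict from a fitted SVR model
#'
#' Evaluates `f(x) = sum_{i in support} theta_i K(x_i, x) + b`.  Only
#' support vectors contribute: removing zero-coefficient training rows
#' leaves predictions unchanged.
#'
#' @param object an `svr_model`.
#' @param newdata numeric matrix (or vector for one-dimensional problems)
#'   with the training feature dimension.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  Z <- as_points(newdata)
  if (ncol(Z) != ncol(object$X))
    stop("'newdata' dimension does not match the training features",
         call. = FALSE)
  sv <- object$support
  if (length(sv) == 0L) return(rep(object$bias, nrow(Z)))
  Kxz <- kernel_matrix(object$kernel, object$X[sv, , drop = FALSE], Z)
  drop(crossprod(Kxz, object$theta[sv])) + object$bias
}

#' Dual objective of an SVR coefficient vector
#'
#' Computes
#' `sum_i y_i theta_i - eps * sum_i (alpha_i + alpha_star_i)
#'  - 1/2 theta' K theta`,
#' the quantity the dual solver maximizes.  With the minimal-norm
#' decomposition, `alpha_i + alpha_star_i = |theta_i|`.
#'
#' @param model an `svr_model`.
#' @return a single number.
#' @export
dual_objective <- function(model) {
  stopifnot(inherits(model, "svr_model"))
  K <- kernel_matrix(model$kernel, model$X)
  sum(model$y * model$theta) -
    model$epsilon * sum(model$alpha + model$alpha_star) -
    0.5 * drop(crossprod(model$theta, K %*% model$theta))
}

dual_objective_raw <- function(theta, y, K, epsilon) {
  sum(y * theta) - epsilon * sum(abs(theta)) -
    0.5 * drop(crossprod(theta, K %*% theta))
}

#' Maximal violation of the SVR optimality conditions
#'
#' Measures how far a coefficient vector is from satisfying the
#' Karush-Kuhn-Tucker conditions of the epsilon-SVR dual: box feasibility,
#' the equality constraint `sum_i theta_i = 0`, and complementarity between
#' residuals and multipliers (interior points must lie inside the tube,
#' free support vectors exactly on its boundary, and bound support vectors
#' on or outside it).  A converged solver returns a model whose violation
#' is at most the configured tolerance.
#'
#' @param model an `svr_model`.
#' @param theta optional coefficient vector overriding `model$theta`
#'   (useful for inspecting perturbed coefficients).
#' @param bias optional bias overriding the model's; when `theta` is
#'   supplied and `bias` is not, the bias is recomputed from `theta`.
#' @return the maximal violation, a nonnegative number.
#' @export
kkt_violation <- function(model, theta = NULL, bias = NULL) {
  stopifnot(inherits(model, "svr_model"))
  K <- kernel_matrix(model$kernel, model$X)
  if (is.null(theta)) {
    theta <- model$theta
    if (is.null(bias)) bias <- model$bias
  } else if (is.null(bias)) {
    bias <- tryCatch(
      compute_bias(theta, model$y, K, model$C, model$epsilon),
      error = function(e) model$bias)
  }
  C <- model$C; eps <- model$epsilon
  sv_tol <- 1e-8 * C
  E <- model$y - drop(K %*% theta) - bias   # residuals y - f(x)

  v <- c(max(0, max(theta) - C), max(0, -C - min(theta)), abs(sum(theta)))
  for (i in seq_along(theta)) {
    th <- theta[i]
    if (abs(th) <= sv_tol) {
      v <- c(v, max(0, abs(E[i]) - eps))
    } else if (th >= C - sv_tol) {
      v <- c(v, max(0, eps - E[i]))
    } else if (th <= -C + sv_tol) {
      v <- c(v, max(0, E[i] + eps))
    } else if (th > 0) {
      v <- c(v, abs(E[i] - eps))
    } else {
      v <- c(v, abs(E[i] + eps))
    }
  }
  max(v)
}

#' Bias (offset) of an SVR solution
#'
#' The offset `b` is recovered from the tube-boundary conditions: any free
#' support vector (`0 < |theta_i| < C`) lies exactly on the tube edge, so
#' `b = y_i - (K theta)_i -/+ epsilon` there; `b` is averaged over all free
#' points.  When no free point exists, every observation constrains `b` to
#' an interval and the midpoint of the intersection is used (for the
#' all-zero solution on constant targets this returns the target value).
#'
#' @param theta dual coefficient vector.
#' @param y training responses.
#' @param K symmetric training Gram matrix.
#' @param C box constraint used in the fit.
#' @param epsilon tube half-width used in the fit.
#' @param sv_tol threshold below which a coefficient counts as zero.
#' @return the bias, a single number.
#' @export
compute_bias <- function(theta, y, K, C, epsilon, sv_tol = 1e-8 * C) {
  E <- y - drop(K %*% theta)
  free <- which(abs(theta) > sv_tol & abs(theta) < C - sv_tol)
  if (length(free) > 0L)
    return(mean(E[free] - sign(theta[free]) * epsilon))
  # interval for b from the KKT inequalities at bound/zero points
  lo <- -Inf; hi <- Inf
  for (i in seq_along(theta)) {
    th <- theta[i]
    if (abs(th) <= sv_tol) {          # inside tube: |E - b| <= eps
      lo <- max(lo, E[i] - epsilon); hi <- min(hi, E[i] + epsilon)
    } else if (th > 0) {              # at +C: E - b >= eps
      hi <- min(hi, E[i] - epsilon)
    } else {                          # at -C: E - b <= -eps
      lo <- max(lo, E[i] + epsilon)
    }
  }
  if (!is.finite(lo) && !is.finite(hi)) return(0)
  if (!is.finite(lo)) return(hi)
  if (!is.finite(hi)) return(lo)
  if (lo > hi + 1e-6 * max(1, abs(lo), abs(hi)))
    stop(sprintf(paste0("infeasible bias interval [%.6g, %.6g]; ",
                        "the coefficient vector is not near-optimal"),
                 lo, hi), call. = FALSE)
  (lo + hi) / 2
}
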