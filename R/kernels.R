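#' Kernel specifications
#'
#' A `kernel_spec` is a declarative description of a Mercer kernel: either a
#' base kernel (radial basis, polynomial, or plain inner product) or an
#' admissible composition (convex sum, product, nonnegative scaling).
#' Specs are plain lists so they can be serialized to a flat key-value
#' configuration block and re-parsed without loss
#' (see [kernel_to_config()] / [kernel_from_config()]).
#'
#' The radial basis kernel is evaluated as `exp(-gamma * ||x - z||^2)` with
#' `gamma > 0`.  Only the negated exponent yields a bounded, positive
#' semi-definite similarity; the positive-exponent variant (available via
#' `negate = FALSE`) is unbounded, fails the empirical admissibility check,
#' and exists solely so that the failure can be demonstrated.
#'
#' @param gamma positive width parameter of the radial basis kernel.
#' @param negate logical; if `FALSE`, evaluate the inadmissible
#'   positive-exponent form `exp(+gamma d^2)`.  For demonstration only.
#' @return an object of class `kernel_spec`.
#' @examples
#' k <- kernel_rbf(gamma = 1)
#' kernel_eval(k, c(0, 0), c(1, 0))  # exp(-1)
#' @export
kernel_rbf <- function(gamma = 1, negate = TRUE) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
    stop("'gamma' must be a single positive number", call. = FALSE)
  new_kernel_spec(list(kind = "rbf", gamma = as.numeric(gamma),
                       negate = isTRUE(negate)))
}

#' @rdname kernel_rbf
#' @param sigma positive scale parameter of the polynomial kernel
#'   `(1 + sigma * <x, z>)^p`.
#' @param p positive integer polynomial degree.
#' @export
kernel_poly <- function(sigma = 1, p = 2L) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p != round(p))
    stop("'p' must be a positive integer", call. = FALSE)
  new_kernel_spec(list(kind = "poly", sigma = as.numeric(sigma), p = as.integer(p)))
}

#' @rdname kernel_rbf
#' @details `kernel_linear()` is the plain inner product `<x, z>`; it is kept
#'   for hand-solvable regression fixtures rather than for modeling.
#' @export
kernel_linear <- function() {
  new_kernel_spec(list(kind = "linear_raw"))
}

#' @rdname kernel_rbf
#' @param beta sum-mixture weight, strictly inside (0, 1): the mixture is
#'   `beta * K_rbf + (1 - beta) * K_poly`, weighting the local (radial)
#'   component against the global (polynomial) one.
#' @export
kernel_sum_mixture <- function(gamma = 1, sigma = 1, p = 2L, beta = 0.8) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0 || beta >= 1)
    stop("'beta' must lie strictly inside (0, 1)", call. = FALSE)
  new_kernel_spec(list(kind = "sum_mixture", beta = as.numeric(beta),
                       children = list(kernel_rbf(gamma), kernel_poly(sigma, p))))
}

#' @rdname kernel_rbf
#' @export
kernel_product_mixture <- function(gamma = 1, sigma = 1, p = 2L) {
  new_kernel_spec(list(kind = "product_mixture",
                       children = list(kernel_rbf(gamma), kernel_poly(sigma, p))))
}

#' @rdname kernel_rbf
#' @param kernel a `kernel_spec` to rescale.
#' @param scale nonnegative multiplier; nonnegative scaling preserves
#'   admissibility.
#' @export
kernel_scaled <- function(kernel, scale) {
  stopifnot(inherits(kernel, "kernel_spec"))
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale < 0)
    stop("'scale' must be a single nonnegative number", call. = FALSE)
  new_kernel_spec(list(kind = "scaled", scale = as.numeric(scale),
                       children = list(kernel)))
}

new_kernel_spec <- function(fields) {
  structure(fields, class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(format_kernel_spec(x), "\n")
  invisible(x)
}

format_kernel_spec <- function(k) {
  switch(k$kind,
    rbf = sprintf("rbf(gamma = %g%s)", k$gamma,
                  if (isTRUE(k$negate)) "" else ", positive exponent [inadmissible]"),
    poly = sprintf("poly(sigma = %g, p = %d)", k$sigma, k$p),
    linear_raw = "linear_raw",
    sum_mixture = sprintf("%g * %s + %g * %s", k$beta,
                          format_kernel_spec(k$children[[1L]]), 1 - k$beta,
                          format_kernel_spec(k$children[[2L]])),
    product_mixture = sprintf("%s * %s", format_kernel_spec(k$children[[1L]]),
                              format_kernel_spec(k$children[[2L]])),
    scaled = sprintf("%g * %s", k$scale, format_kernel_spec(k$children[[1L]])),
    stop("unknown kernel kind: ", k$kind))
}

#' Evaluate a kernel on a pair of points
#'
#' @param kernel a [kernel_spec][kernel_rbf].
#' @param x,z numeric vectors of equal length.
#' @return a single numeric kernel value.
#' @export
kernel_eval <- function(kernel, x, z) {
  stopifnot(inherits(kernel, "kernel_spec"))
  x <- as.numeric(x); z <- as.numeric(z)
  if (length(x) != length(z))
    stop("'x' and 'z' must have the same dimension", call. = FALSE)
  as.vector(kernel_matrix(kernel, matrix(x, nrow = 1L),
                          matrix(z, nrow = 1L)))
}

#' Gram matrix of a kernel over point sets
#'
#' Materializes the matrix `K[i, j] = K(X[i, ], Z[j, ])`.  When `Z` is
#' omitted the matrix is the symmetric Gram matrix of `X` and carries the
#' attribute `symmetric = TRUE`.
#'
#' @inheritParams kernel_eval
#' @param X,Z numeric matrices with points as rows and a common number of
#'   columns.  `Z` defaults to `X`.
#' @return an `n x m` numeric matrix with attributes `kernel` and
#'   `symmetric`.
#' @export
kernel_matrix <- function(kernel, X, Z = NULL) {
  stopifnot(inherits(kernel, "kernel_spec"))
  X <- as_points(X)
  symmetric <- is.null(Z)
  Z <- if (symmetric) X else as_points(Z)
  if (nrow(X) == 0L || nrow(Z) == 0L)
    stop("empty point set", call. = FALSE)
  if (ncol(X) != ncol(Z))
    stop("'X' and 'Z' must share the same dimension", call. = FALSE)
  K <- kernel_matrix_impl(kernel, X, Z)
  if (symmetric) K <- (K + t(K)) / 2  # remove floating asymmetry
  structure(K, kernel = kernel, symmetric = symmetric)
}

kernel_matrix_impl <- function(k, X, Z) {
  switch(k$kind,
    rbf = {
      d2 <- sq_dist(X, Z)
      s <- if (isTRUE(k$negate)) -k$gamma else k$gamma
      exp(s * d2)
    },
    poly = (1 + k$sigma * tcrossprod(X, Z))^k$p,
    linear_raw = tcrossprod(X, Z),
    sum_mixture = k$beta * kernel_matrix_impl(k$children[[1L]], X, Z) +
      (1 - k$beta) * kernel_matrix_impl(k$children[[2L]], X, Z),
    product_mixture = kernel_matrix_impl(k$children[[1L]], X, Z) *
      kernel_matrix_impl(k$children[[2L]], X, Z),
    scaled = k$scale * kernel_matrix_impl(k$children[[1L]], X, Z),
    stop("unknown kernel kind: ", k$kind))
}

as_points <- function(X) {
  if (is.null(dim(X))) X <- matrix(as.numeric(X), ncol = 1L)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X)))
    stop("points must be finite and non-missing", call. = FALSE)
  X
}

# squared Euclidean distances between rows of X and rows of Z
sq_dist <- function(X, Z) {
  xx <- rowSums(X^2)
  zz <- rowSums(Z^2)
  d2 <- outer(xx, zz, "+") - 2 * tcrossprod(X, Z)
  d2[d2 < 0] <- 0
  d2
}

#' Empirical Mercer admissibility check
#'
#' A kernel is admissible (Mercer) when every Gram matrix it produces is
#' positive semi-definite.  This check builds the symmetric Gram matrix on a
#' point set and inspects its spectrum; the pass threshold scales with the
#' matrix size to absorb floating-point eigenvalue noise.
#'
#' @inheritParams kernel_matrix
#' @param tol nonnegative tolerance; the check passes when the minimum
#'   eigenvalue is at least `-tol * n`.
#' @return a list with `min_eigenvalue`, `n`, `tol`, and logical `pass`.
#' @examples
#' ok <- check_admissible(kernel_rbf(1), matrix(rnorm(20), 10, 2))
#' ok$pass
#' # the positive-exponent radial form is not a valid kernel:
#' bad <- check_admissible(kernel_rbf(1, negate = FALSE), matrix(0:2, 3, 1))
#' bad$pass
#' @export
check_admissible <- function(kernel, X, tol = 1e-8) {
  X <- as_points(X)
  if (nrow(X) < 2L)
    stop("need at least two points to assess admissibility", call. = FALSE)
  K <- kernel_matrix(kernel, X)
  if (max(abs(K - t(K))) > 1e-10 * max(1, max(abs(K))))
    stop("internal error: Gram matrix is not symmetric", call. = FALSE)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  n <- nrow(X)
  list(min_eigenvalue = min(ev), n = n, tol = tol,
       pass = min(ev) >= -tol * n)
}

#' Distance induced by a kernel in its feature space
#'
#' Any admissible kernel is an inner product in a feature space, so it
#' induces the distance
#' `d(x, z) = sqrt(K(x, x) + K(z, z) - 2 K(x, z))` between feature images.
#' Small negative values of the radicand arising from floating-point error
#' are clamped to zero.
#'
#' @inheritParams kernel_eval
#' @return a single nonnegative number.
#' @export
induced_feature_distance <- function(kernel, x, z) {
  v <- kernel_eval(kernel, x, x) + kernel_eval(kernel, z, z) -
    2 * kernel_eval(kernel, x, z)
  sqrt(max(0, v))
}

#' Serialize a kernel spec to a flat configuration block
#'
#' Kernel specs round-trip through a flat named list whose keys are
#' `kind`, `gamma`, `sigma`, `p`, `beta`, and `scale`.  The sum and product
#' mixtures are stored with the parameters of their radial and polynomial
#' components; a `scaled` kernel nests its child's keys under the prefix
#' `child.`.
#'
#' @inheritParams kernel_eval
#' @return `kernel_to_config()`: a named list of atomic values.
#' @export
kernel_to_config <- function(kernel) {
  stopifnot(inherits(kernel, "kernel_spec"))
  switch(kernel$kind,
    rbf = list(kind = "rbf", gamma = kernel$gamma, negate = kernel$negate),
    poly = list(kind = "poly", sigma = kernel$sigma, p = kernel$p),
    linear_raw = list(kind = "linear_raw"),
    sum_mixture = list(kind = "sum_mixture",
                       gamma = kernel$children[[1L]]$gamma,
                       sigma = kernel$children[[2L]]$sigma,
                       p = kernel$children[[2L]]$p,
                       beta = kernel$beta),
    product_mixture = list(kind = "product_mixture",
                           gamma = kernel$children[[1L]]$gamma,
                           sigma = kernel$children[[2L]]$sigma,
                           p = kernel$children[[2L]]$p),
    scaled = {
      child <- kernel_to_config(kernel$children[[1L]])
      names(child) <- paste0("child.", names(child))
      c(list(kind = "scaled", scale = kernel$scale), child)
    },
    stop("unknown kernel kind: ", kernel$kind))
}

#' @rdname kernel_to_config
#' @param config a named list (or coercible vector) as produced by
#'   `kernel_to_config()`.
#' @return `kernel_from_config()`: a `kernel_spec`.
#' @export
kernel_from_config <- function(config) {
  config <- as.list(config)
  kind <- as.character(config$kind)
  num <- function(key, default = NULL) {
    if (is.null(config[[key]])) default else as.numeric(config[[key]])
  }
  switch(kind,
    rbf = kernel_rbf(num("gamma", 1),
                     negate = !identical(as.logical(config$negate), FALSE)),
    poly = kernel_poly(num("sigma", 1), as.integer(num("p", 2))),
    linear_raw = kernel_linear(),
    sum_mixture = kernel_sum_mixture(num("gamma", 1), num("sigma", 1),
                                     as.integer(num("p", 2)), num("beta", 0.8)),
    product_mixture = kernel_product_mixture(num("gamma", 1), num("sigma", 1),
                                             as.integer(num("p", 2))),
    scaled = {
      child_keys <- grep("^child\\.", names(config), value = TRUE)
      child <- stats::setNames(config[child_keys],
                               sub("^child\\.", "", child_keys))
      kernel_scaled(kernel_from_config(child), num("scale"))
    },
    stop("unknown kernel kind: ", kind))
}

#' Build a kernel spec from a kind name and shared parameters
#'
#' Convenience dispatcher used by the tuning and pipeline layers: maps a
#' kernel kind name plus the flat parameter set (`gamma`, `sigma`, `p`,
#' `beta`) to the corresponding spec.
#'
#' @param kind one of `"rbf"`, `"poly"`, `"linear_raw"`, `"sum_mixture"`,
#'   `"product_mixture"`.
#' @param gamma,sigma,p,beta kernel parameters; unused entries are ignored.
#' @return a `kernel_spec`.
#' @export
kernel_from_kind <- function(kind, gamma = 1, sigma = 1, p = 2L, beta = 0.8) {
  switch(kind,
    rbf = kernel_rbf(gamma),
    poly = kernel_poly(sigma, p),
    linear_raw = kernel_linear(),
    sum_mixture = kernel_sum_mixture(gamma, sigma, p, beta),
    product_mixture = kernel_product_mixture(gamma, sigma, p),
    stop("unknown kernel kind: ", kind))
}
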