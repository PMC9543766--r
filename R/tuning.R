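#' Hyperparameter grids for SVR tuning
#'
#' Default grids follow the tuning protocol: `epsilon` over 0, 0.1, ..., 1
#' and cost `C` over 2^2, 2^3, ..., 2^9 (88 grid points).  Kernel
#' parameters default to single values at search time (`gamma = 1/d` and
#' `sigma = 1/d`, the usual dimension-normalized scaling; `degree = 2`,
#' `beta = 0.8`) and may be given as vectors to
#' be searched exhaustively as well.
#'
#' @param epsilon nonnegative tube half-widths to try.
#' @param cost positive box-constraint values to try.
#' @param gamma optional radial-basis widths (default `1/d` at search
#'   time).
#' @param sigma optional polynomial scales (default 1).
#' @param degree optional polynomial degrees (default 2).
#' @param beta sum-mixture weights in (0, 1) (default fixed at 0.8; see
#'   [select_beta()] for the dedicated mixture-weight search).
#' @return a list of class `tuning_grid`.
#' @export
tuning_grid <- function(epsilon = seq(0, 1, by = 0.1),
                        cost = 2^(2:9),
                        gamma = NULL, sigma = NULL, degree = NULL,
                        beta = 0.8) {
  stopifnot(length(epsilon) >= 1L, all(epsilon >= 0),
            length(cost) >= 1L, all(cost > 0),
            length(beta) >= 1L, all(beta > 0 & beta < 1))
  structure(list(epsilon = as.numeric(epsilon), cost = as.numeric(cost),
                 gamma = gamma, sigma = sigma, degree = degree,
                 beta = as.numeric(beta)),
            class = "tuning_grid")
}

#' Exhaustive grid search for SVR hyperparameters
#'
#' Fits one SVR per grid point on the tuning data and scores it on the
#' held-out validation data.  The winner minimizes validation RMSE; ties
#' are broken in favour of the smaller cost, then the smaller epsilon
#' (preferring flatter, sparser models).  Grid points whose fit fails to
#' converge are flagged in the score table and excluded from selection;
#' the search errors only if every point fails.
#'
#' @param X_train,y_train data the candidate models are fitted on.
#' @param X_val,y_val disjoint validation data used for scoring.
#' @param kernel_kind one of `"rbf"`, `"poly"`, `"linear_raw"`,
#'   `"sum_mixture"`, `"product_mixture"`.
#' @param grid a [tuning_grid()].
#' @param control an [svr_control()]; admissibility is checked once per
#'   kernel-parameter combination rather than per fit.
#' @return a list of class `svr_tuning` with `best` (the winning
#'   parameter row), `score_table` (one row per grid point with validation
#'   MAE/RMSE/R-squared), `kernel_kind`, and `selection_metric`.
#' @export
grid_search <- function(X_train, y_train, X_val, y_val, kernel_kind,
                        grid = tuning_grid(), control = svr_control()) {
  stopifnot(inherits(grid, "tuning_grid"))
  X_train <- as_points(X_train); X_val <- as_points(X_val)
  d <- ncol(X_train)
  gamma_vals <- if (is.null(grid$gamma)) 1 / d else grid$gamma
  sigma_vals <- if (is.null(grid$sigma)) 1 / d else grid$sigma
  degree_vals <- if (is.null(grid$degree)) 2L else grid$degree
  beta_vals <- if (kernel_kind == "sum_mixture") grid$beta else NA_real_

  params <- expand.grid(epsilon = grid$epsilon, C = grid$cost,
                        gamma = gamma_vals, sigma = sigma_vals,
                        degree = degree_vals, beta = beta_vals,
                        KEEP.OUT.ATTRS = FALSE)
  fit_control <- control
  fit_control$check_kernel <- FALSE

  kernel_cache_key <- ""
  kernel <- NULL; K_train <- NULL
  rows <- vector("list", nrow(params))
  for (g in seq_len(nrow(params))) {
    pr <- params[g, ]
    key <- paste(pr$gamma, pr$sigma, pr$degree, pr$beta)
    if (!identical(key, kernel_cache_key)) {
      kernel <- kernel_from_kind(kernel_kind, gamma = pr$gamma,
                                 sigma = pr$sigma, p = pr$degree,
                                 beta = if (is.na(pr$beta)) 0.8 else pr$beta)
      K_train <- kernel_matrix(kernel, X_train)
      if (control$check_kernel && nrow(X_train) >= 2L) {
        adm <- check_admissible(kernel, X_train)
        if (!adm$pass)
          stop("kernel is not admissible on the tuning data", call. = FALSE)
      }
      kernel_cache_key <- key
    }
    fit <- tryCatch(
      svr_fit(X_train, y_train, kernel, C = pr$C, epsilon = pr$epsilon,
              control = fit_control),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[g]] <- cbind(pr, MAE = NA_real_, RMSE = NA_real_,
                         R2_ratio = NA_real_, converged = FALSE)
    } else {
      pred <- predict(fit, X_val)
      rows[[g]] <- cbind(pr, MAE = mae(y_val, pred),
                         RMSE = rmse(y_val, pred),
                         R2_ratio = if (stats::var(y_val) > 0)
                           r2_ratio(y_val, pred) else NA_real_,
                         converged = TRUE)
    }
  }
  score_table <- do.call(rbind, rows)
  rownames(score_table) <- NULL
  ok <- which(score_table$converged)
  if (length(ok) == 0L)
    stop("no grid point converged", call. = FALSE)
  cand <- score_table[ok, ]
  best <- cand[order(cand$RMSE, cand$C, cand$epsilon), ][1L, ]
  structure(list(best = best, score_table = score_table,
                 kernel_kind = kernel_kind,
                 selection_metric = "validation RMSE"),
            class = "svr_tuning")
}

#' @export
print.svr_tuning <- function(x, ...) {
  cat("SVR grid search (", x$kernel_kind, " kernel, ",
      nrow(x$score_table), " grid points, selected by ",
      x$selection_metric, ")\n", sep = "")
  cat("best:\n")
  print(x$best, row.names = FALSE)
  invisible(x)
}

# build the kernel_spec encoded by one score-table row
kernel_from_best <- function(kernel_kind, best) {
  kernel_from_kind(kernel_kind, gamma = best$gamma, sigma = best$sigma,
                   p = best$degree,
                   beta = if (is.na(best$beta)) 0.8 else best$beta)
}

#' Mixture-weight selection for the sum kernel
#'
#' Searches the convex-combination weight `beta` of the sum-mixture kernel
#' `beta * K_rbf + (1 - beta) * K_poly` over a grid inside (0, 1),
#' selecting the weight that minimizes validation RMSE at fixed values of
#' the remaining hyperparameters.
#'
#' @inheritParams grid_search
#' @param beta_values candidate weights, default 0.1, 0.2, ..., 0.9.
#' @param gamma,sigma,degree kernel parameters held fixed during the
#'   search (`gamma` and `sigma` default to `1/d`).
#' @param epsilon,C SVR parameters held fixed.
#' @return a list with `beta` (the selected weight) and `score_table`.
#' @export
select_beta <- function(X_train, y_train, X_val, y_val,
                        beta_values = seq(0.1, 0.9, by = 0.1),
                        gamma = NULL, sigma = NULL, degree = 2L,
                        epsilon = 0.1, C = 16, control = svr_control()) {
  stopifnot(all(beta_values > 0 & beta_values < 1))
  X_train <- as_points(X_train)
  if (is.null(gamma)) gamma <- 1 / ncol(X_train)
  if (is.null(sigma)) sigma <- 1 / ncol(X_train)
  res <- grid_search(X_train, y_train, X_val, y_val, "sum_mixture",
                     grid = tuning_grid(epsilon = epsilon, cost = C,
                                        gamma = gamma, sigma = sigma,
                                        degree = degree, beta = beta_values),
                     control = control)
  list(beta = res$best$beta, score_table = res$score_table)
}

#' Independent per-group tuning and fitting
#'
#' Runs the stratified analysis: patients are partitioned into the four
#' gender-by-age groups, and within each group an SVR with the requested
#' kernel (product mixture with polynomial degree 2 by default) is tuned
#' and fitted independently on voice-only features.  Within each group the
#' grid candidates are fitted on the group's tuning rows and validated on
#' its training rows; the winning parameters are refitted on the training
#' rows and evaluated on both training and test rows.
#'
#' @param dataset a telemonitoring data frame.
#' @param split a `split_assignment` over `dataset` (see
#'   [split_patient_proportional()]).
#' @param kernel_kind kernel for the group models (default
#'   `"product_mixture"`).
#' @param grid a [tuning_grid()]; `degree` defaults to 2.
#' @param target `"total"` or `"motor"`.
#' @param age_threshold age cut for [assign_groups()].
#' @param feature_set features for the group models (default
#'   `"voice_only"`, i.e. demographics are dropped because the grouping
#'   already encodes them).
#' @param control an [svr_control()].
#' @return a list of class `svr_group_fit` with `groups` (per-group model,
#'   tuning result, and row indices), `metrics` (train/test metric rows per
#'   group), and `average` (unweighted across-group mean of each metric,
#'   split by role).  Empty groups are skipped with a warning.
#' @export
tune_per_group <- function(dataset, split, kernel_kind = "product_mixture",
                           grid = tuning_grid(degree = 2L),
                           target = "total", age_threshold = 65,
                           feature_set = "voice_only",
                           control = svr_control()) {
  assert_telemonitoring_schema(dataset)
  stopifnot(inherits(split, "split_assignment"))
  group <- assign_groups(dataset, age_threshold)
  out_groups <- list()
  metric_rows <- list()
  for (g in 1:4) {
    idx <- which(group == g)
    if (length(idx) == 0L) {
      warning("group ", g, " is empty; skipped", call. = FALSE)
      next
    }
    sub <- dataset[idx, , drop = FALSE]
    lab <- split$label[idx]
    tr <- which(lab == "train"); tu <- which(lab == "tune")
    te <- which(lab == "test")
    if (length(tr) < 2L || length(tu) < 2L || length(te) < 1L) {
      warning("group ", g, " has too few rows in some split part; skipped",
              call. = FALSE)
      next
    }
    fm <- feature_matrix(sub, feature_set = feature_set, target = target,
                         standardize = TRUE, train_rows = tr)
    tun <- grid_search(fm$X[tu, , drop = FALSE], fm$y[tu],
                       fm$X[tr, , drop = FALSE], fm$y[tr],
                       kernel_kind, grid = grid, control = control)
    kernel <- kernel_from_best(kernel_kind, tun$best)
    model <- svr_fit(fm$X[tr, , drop = FALSE], fm$y[tr], kernel,
                     C = tun$best$C, epsilon = tun$best$epsilon,
                     control = control)
    pred_tr <- predict(model, fm$X[tr, , drop = FALSE])
    pred_te <- predict(model, fm$X[te, , drop = FALSE])
    metric_rows[[length(metric_rows) + 1L]] <-
      rbind(metrics_row(fm$y[tr], pred_tr, model = kernel_kind,
                        role = "train", group = g),
            metrics_row(fm$y[te], pred_te, model = kernel_kind,
                        role = "test", group = g))
    out_groups[[as.character(g)]] <-
      list(group = g, model = model, tuning = tun, rows = idx,
           scaler = fm$scaler, features = fm$features)
  }
  if (length(metric_rows) == 0L)
    stop("no group could be fitted", call. = FALSE)
  metrics <- do.call(rbind, metric_rows)
  rownames(metrics) <- NULL
  average <- do.call(rbind, lapply(split(metrics, metrics$role), function(df) {
    avg <- group_average_metrics(df)
    avg$role <- df$role[1L]
    avg
  }))
  rownames(average) <- NULL
  structure(list(groups = out_groups, metrics = metrics, average = average,
                 kernel_kind = kernel_kind, target = target,
                 age_threshold = age_threshold),
            class = "svr_group_fit")
}
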