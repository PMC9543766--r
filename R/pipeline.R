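#' End-to-end SVR analysis of a telemonitoring dataset
#'
#' Runs the full modeling protocol on one dataset: a seeded
#' patient-proportional tune/train/test split, standardization fitted on
#' the training rows, an epsilon-by-cost grid search (candidates fitted on
#' the tuning rows and validated on the training rows), a final fit of the
#' winning configuration on the training rows, and train/test metrics.
#'
#' @param dataset a telemonitoring data frame (from
#'   [read_telemonitoring_csv()] or [synth_generate()]).
#' @param kernel_kind kernel family to tune and fit (default
#'   `"product_mixture"`).
#' @param feature_set `"pooled"` (voice + age + sex), `"voice_only"`, or
#'   `"custom"`.
#' @param custom_features columns for `feature_set = "custom"`.
#' @param target `"total"` or `"motor"` UPDRS.
#' @param fractions split fractions, see [split_patient_proportional()].
#' @param seed seed for the split.
#' @param grid a [tuning_grid()]; pass a single-point grid to skip tuning.
#' @param control an [svr_control()].
#' @param tune_mode forwarded to [split_patient_proportional()].
#' @return a list of class `svr_pipeline` with `model`, `tuning`, `split`,
#'   `scaler`, `metrics` (train and test rows), `kernel_kind`, `features`,
#'   and `seed`.
#' @export
run_svr_pipeline <- function(dataset, kernel_kind = "product_mixture",
                             feature_set = "pooled", custom_features = NULL,
                             target = "total",
                             fractions = c(tune = 0.08, train = 0.72,
                                           test = 0.20),
                             seed = 1L, grid = tuning_grid(),
                             control = svr_control(),
                             tune_mode = "patient") {
  assert_telemonitoring_schema(dataset)
  split <- split_patient_proportional(dataset, fractions = fractions,
                                      seed = seed, tune_mode = tune_mode)
  tr <- which(split$label == "train")
  tu <- which(split$label == "tune")
  te <- which(split$label == "test")
  fm <- feature_matrix(dataset, feature_set = feature_set,
                       custom_features = custom_features, target = target,
                       standardize = TRUE, train_rows = tr)
  tun <- grid_search(fm$X[tu, , drop = FALSE], fm$y[tu],
                     fm$X[tr, , drop = FALSE], fm$y[tr],
                     kernel_kind, grid = grid, control = control)
  kernel <- kernel_from_best(kernel_kind, tun$best)
  model <- svr_fit(fm$X[tr, , drop = FALSE], fm$y[tr], kernel,
                   C = tun$best$C, epsilon = tun$best$epsilon,
                   control = control)
  metrics <- rbind(
    metrics_row(fm$y[tr], predict(model, fm$X[tr, , drop = FALSE]),
                model = kernel_kind, role = "train"),
    metrics_row(fm$y[te], predict(model, fm$X[te, , drop = FALSE]),
                model = kernel_kind, role = "test"))
  structure(list(model = model, tuning = tun, split = split,
                 scaler = fm$scaler, metrics = metrics,
                 kernel_kind = kernel_kind, features = fm$features,
                 X = fm$X, y = fm$y, target = target, seed = seed),
            class = "svr_pipeline")
}

#' @export
print.svr_pipeline <- function(x, ...) {
  cat("SVR pipeline (", x$kernel_kind, " kernel, seed ", x$seed, ")\n",
      sep = "")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Persist and restore a fitted SVR model
#'
#' The model file is a single self-describing serialized list holding the
#' dual coefficients, bias, support vectors, kernel configuration (via
#' [kernel_to_config()]), scaler statistics, and the feature-name
#' fingerprint, so that loading it reproduces in-memory predictions
#' exactly.
#'
#' @param model an `svr_model`.
#' @param path file path for the model.
#' @param scaler optional `feature_scaler` stored alongside.
#' @param features optional character vector of feature names.
#' @return `svr_save()`: `path` invisibly; `svr_load()`: a list with
#'   `model`, `scaler`, `features`.
#' @export
svr_save <- function(model, path, scaler = NULL, features = NULL) {
  stopifnot(inherits(model, "svr_model"))
  payload <- list(format = "mixsvr-model-1",
                  kernel_config = kernel_to_config(model$kernel),
                  model = model, scaler = scaler, features = features)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname svr_save
#' @export
svr_load <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "mixsvr-model-1"))
    stop("'", path, "' is not a mixsvr model file", call. = FALSE)
  payload$model$kernel <- kernel_from_config(payload$kernel_config)
  list(model = payload$model, scaler = payload$scaler,
       features = payload$features)
}

#' Gain table of grouped models against a reference model
#'
#' For every group and metric, computes the percentage gain of the grouped
#' model relative to the reference (pooled) model's value of the same
#' metric and role: percentage decrease for MAE/RMSE, percentage increase
#' for the R-squared columns.
#'
#' @param group_metrics metric rows per group (from
#'   [tune_per_group()]`$metrics`).
#' @param reference_metrics metric rows of the reference model with
#'   matching `role` values (e.g. a pooled fit's metrics).
#' @return a data frame with one row per group and role, metric columns
#'   holding gains in percent.
#' @export
gain_table <- function(group_metrics, reference_metrics) {
  cols <- c("MAE", "RMSE", "R2_ratio", "R2_standard")
  rows <- lapply(seq_len(nrow(group_metrics)), function(i) {
    role <- group_metrics$role[i]
    ref <- reference_metrics[reference_metrics$role == role, ]
    if (nrow(ref) != 1L)
      stop("reference metrics must contain exactly one row per role",
           call. = FALSE)
    vals <- vapply(cols, function(cl) {
      dir <- if (cl %in% c("MAE", "RMSE")) "lower_is_better"
             else "higher_is_better"
      gain_percentage(ref[[cl]], group_metrics[[cl]][i], dir)
    }, numeric(1))
    cbind(data.frame(group = group_metrics$group[i], role = role,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(vals)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
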