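#' Regression performance metrics
#'
#' Mean absolute error, root mean squared error, and two variants of the
#' coefficient of determination.  `r2_ratio()` is the explained-variation
#' ratio `sum((yhat - ybar)^2) / sum((y - ybar)^2)` with `ybar` the mean of
#' the observed responses; it is nonnegative and — unlike the conventional
#' `1 - RSS/TSS` computed by [r2_standard()] — can exceed 1 when the
#' predictions are more dispersed than the observations.  Both variants are
#' reported side by side by the pipeline so the ratio form can be compared
#' against the conventional one.
#'
#' @param y numeric vector of observed values.
#' @param yhat numeric vector of predictions, same length as `y`.
#' @return a single number.
#' @examples
#' mae(c(0, 2), c(1, 1))       # 1
#' rmse(c(0, 2), c(1, 1))      # 1
#' r2_ratio(c(0, 1), c(-1, 2)) # 9: over-dispersed predictions exceed 1
#' r2_standard(c(0, 1), c(-1, 2)) # -3
#' @export
mae <- function(y, yhat) {
  check_metric_args(y, yhat)
  mean(abs(yhat - y))
}

#' @rdname mae
#' @export
rmse <- function(y, yhat) {
  check_metric_args(y, yhat)
  sqrt(mean((yhat - y)^2))
}

#' @rdname mae
#' @export
r2_ratio <- function(y, yhat) {
  check_metric_args(y, yhat)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0)
    stop("'y' is constant; the explained-variation ratio is undefined",
         call. = FALSE)
  sum((yhat - mean(y))^2) / tss
}

#' @rdname mae
#' @export
r2_standard <- function(y, yhat) {
  check_metric_args(y, yhat)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0)
    stop("'y' is constant; R-squared is undefined", call. = FALSE)
  1 - sum((y - yhat)^2) / tss
}

check_metric_args <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("'y' and 'yhat' must have the same length", call. = FALSE)
  if (length(y) < 1L) stop("need at least one observation", call. = FALSE)
  invisible(TRUE)
}

#' Percentage gain of a metric relative to a reference model
#'
#' For error metrics (`direction = "lower_is_better"`) the gain is the
#' percentage decrease `100 * (reference - value) / reference`; for metrics
#' where larger is better the gain is the percentage increase
#' `100 * (value - reference) / reference`.
#'
#' @param reference metric value of the reference model (nonzero).
#' @param value metric value of the model under comparison.
#' @param direction `"lower_is_better"` (errors such as MAE/RMSE) or
#'   `"higher_is_better"` (e.g. R-squared).
#' @return the gain in percent.
#' @examples
#' gain_percentage(6.220, 2.19)  # 64.79% decrease in RMSE
#' @export
gain_percentage <- function(reference, value,
                            direction = c("lower_is_better",
                                          "higher_is_better")) {
  direction <- match.arg(direction)
  if (!is.numeric(reference) || reference == 0)
    stop("'reference' must be a nonzero number", call. = FALSE)
  if (direction == "lower_is_better")
    100 * (reference - value) / reference
  else
    100 * (value - reference) / reference
}

#' Row of the standard metrics for one model and data role
#'
#' @param y,yhat observed and predicted responses.
#' @param model name of the model.
#' @param role data role, e.g. `"train"` or `"test"`.
#' @param group group label, `"pooled"` or a group id.
#' @return a one-row data frame with columns `model`, `role`, `group`,
#'   `MAE`, `RMSE`, `R2_ratio`, `R2_standard`.
#' @export
metrics_row <- function(y, yhat, model = "model", role = "train",
                        group = "pooled") {
  data.frame(model = model, role = role, group = as.character(group),
             MAE = mae(y, yhat), RMSE = rmse(y, yhat),
             R2_ratio = r2_ratio(y, yhat),
             R2_standard = r2_standard(y, yhat),
             stringsAsFactors = FALSE)
}

#' Unweighted average of per-group metric rows
#'
#' Averages each metric column arithmetically across groups, as done when
#' summarizing the per-group models into one line.
#'
#' @param rows a data frame of metric rows (as from [metrics_row()]) or a
#'   data frame with numeric metric columns.
#' @param metric_cols names of the columns to average.
#' @return a one-row data frame of column means with `group = "average"`.
#' @examples
#' tab <- data.frame(MAE = c(2.53, 1.58, 1.85, 1.41))
#' group_average_metrics(tab)$MAE  # 1.8425
#' @export
group_average_metrics <- function(rows,
                                  metric_cols = intersect(
                                    c("MAE", "RMSE", "R2_ratio",
                                      "R2_standard"), names(rows))) {
  if (nrow(rows) < 1L) stop("need at least one group row", call. = FALSE)
  out <- as.data.frame(lapply(rows[metric_cols], mean),
                       stringsAsFactors = FALSE)
  out$group <- "average"
  out[c("group", metric_cols)]
}

#' Per-patient trajectory report
#'
#' Assembles, for one subject, the time-ordered record of observed UPDRS
#' values together with the model's fitted values on training rows and
#' predictions on tuning/test rows — the tabular form of a per-patient
#' progression plot.
#'
#' @param model an `svr_model` fitted on the training rows.
#' @param dataset a telemonitoring data frame (see
#'   [read_telemonitoring_csv()]).
#' @param split a `split_assignment` from [split_patient_proportional()].
#' @param subject_id subject identifier present in the dataset's
#'   `subject#` column.
#' @param features matrix of model-ready features for every row of
#'   `dataset` (same preprocessing as used in the fit).
#' @param target name of the target column, `"total_UPDRS"` or
#'   `"motor_UPDRS"`.
#' @return a data frame ordered by `test_time` with columns `subject`,
#'   `test_time`, `actual`, `predicted`, `split`.
#' @export
patient_trajectory_report <- function(model, dataset, split, subject_id,
                                      features, target = "total_UPDRS") {
  stopifnot(inherits(model, "svr_model"))
  idx <- which(dataset[["subject#"]] == subject_id)
  if (length(idx) == 0L)
    stop("unknown subject: ", subject_id, call. = FALSE)
  pred <- predict(model, features[idx, , drop = FALSE])
  out <- data.frame(subject = subject_id,
                    test_time = dataset$test_time[idx],
                    actual = dataset[[target]][idx],
                    predicted = pred,
                    split = as.character(split$label[idx]),
                    stringsAsFactors = FALSE)
  out[order(out$test_time), , drop = FALSE]
}
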