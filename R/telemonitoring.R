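#' Canonical telemonitoring column names
#'
#' Column layout of the UCI Parkinson's telemonitoring feature table:
#' subject identity, demographics, days since recruitment, the two UPDRS
#' targets, and 16 voice measures (jitter variants, shimmer variants,
#' noise/harmonicity ratios, and the nonlinear measures RPDE, DFA, PPE).
#'
#' @return `telemonitoring_columns()`: character vector of the 22 column
#'   names; `telemonitoring_voice_features()`: the 16 voice-feature names.
#' @export
telemonitoring_columns <- function() {
  c("subject#", "age", "sex", "test_time", "motor_UPDRS", "total_UPDRS",
    telemonitoring_voice_features())
}

#' @rdname telemonitoring_columns
#' @export
telemonitoring_voice_features <- function() {
  c("Jitter(%)", "Jitter(Abs)", "Jitter:RAP", "Jitter:PPQ5", "Jitter:DDP",
    "Shimmer", "Shimmer(dB)", "Shimmer:APQ3", "Shimmer:APQ5",
    "Shimmer:APQ11", "Shimmer:DDA", "NHR", "HNR", "RPDE", "DFA", "PPE")
}

assert_telemonitoring_schema <- function(df, where = "dataset") {
  want <- telemonitoring_columns()
  missing <- setdiff(want, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s is missing required column(s): %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Read a telemonitoring CSV file
#'
#' Reads the comma-separated telemonitoring feature table (the UCI
#' `parkinsons_updrs.data` layout, or a file written by
#' [write_telemonitoring_csv()]), validates the canonical header, and
#' coerces every column to numeric.  Row order is preserved.  `test_time`
#' may be slightly negative (pre-baseline recordings occur in the source
#' data) and is accepted.
#'
#' @param path path to a CSV file with a header row.
#' @return a data frame with the 22 canonical columns.
#' @export
read_telemonitoring_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", strip.white = TRUE)
  assert_telemonitoring_schema(df, where = paste0("'", path, "'"))
  df <- df[telemonitoring_columns()]
  if (nrow(df) == 0L)
    stop("'", path, "' contains a header but no recordings", call. = FALSE)
  for (col in names(df)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0L)
      stop(sprintf("non-numeric value in column '%s' at row %d", col,
                   bad[1L]), call. = FALSE)
    df[[col]] <- v
  }
  df
}

#' Write a telemonitoring dataset to CSV
#'
#' Emits the canonical header and comma-separated values; the result
#' round-trips exactly through [read_telemonitoring_csv()].
#'
#' @param dataset a data frame with the canonical columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_telemonitoring_csv <- function(dataset, path) {
  assert_telemonitoring_schema(dataset)
  utils::write.csv(dataset[telemonitoring_columns()], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Descriptive statistics of the telemonitoring features
#'
#' Mean, median, and sample standard deviation for every numeric column
#' except the gender indicator (a 0/1 code for which these summaries are
#' not meaningful in the descriptive table).
#'
#' @param dataset a telemonitoring data frame.
#' @return a data frame with columns `feature`, `mean`, `median`, `sd`.
#' @export
describe_features <- function(dataset) {
  assert_telemonitoring_schema(dataset)
  if (nrow(dataset) == 0L) stop("empty dataset", call. = FALSE)
  cols <- setdiff(telemonitoring_columns(), "sex")
  data.frame(
    feature = cols,
    mean = vapply(cols, function(cl) mean(dataset[[cl]]), numeric(1)),
    median = vapply(cols, function(cl) stats::median(dataset[[cl]]),
                    numeric(1)),
    sd = vapply(cols, function(cl) stats::sd(dataset[[cl]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

# evaluate expr with a temporary RNG state seeded by `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# largest-remainder apportionment of n items over `fractions`, ties and
# leftovers resolved by the priority order of `fractions`' names
largest_remainder <- function(n, fractions, priority) {
  exact <- fractions * n
  base <- floor(exact)
  rem <- exact - base
  leftover <- n - sum(base)
  if (leftover > 0) {
    prio_rank <- match(names(fractions), priority)
    ord <- order(-rem, prio_rank)
    base[ord[seq_len(leftover)]] <- base[ord[seq_len(leftover)]] + 1
  }
  as.integer(base)
}

#' Patient-proportional split into tuning, training, and test sets
#'
#' Assigns every recording to one of `tune`, `train`, `test` so that each
#' patient contributes the same label proportions as the global fractions,
#' up to largest-remainder rounding of that patient's recording count.
#' Which of a patient's recordings receive which label is random and
#' reproducible by `seed`.  Patients with fewer recordings than labels are
#' allocated by the priority train > test > tune.
#'
#' @param dataset a telemonitoring data frame.
#' @param fractions named numeric vector with entries `tune`, `train`,
#'   `test`; must be positive and sum to 1.
#' @param seed integer seed controlling the random within-patient
#'   assignment.
#' @param tune_mode `"patient"` draws the tuning subset
#'   patient-proportionally like the other labels; `"uniform"` draws it
#'   uniformly at random across all recordings first, then splits the
#'   remainder patient-proportionally between train and test.
#' @return an object of class `split_assignment`: a list with `label`
#'   (factor over `tune`/`train`/`test`, one per recording), `fractions`,
#'   `seed`, and `tune_mode`.
#' @export
split_patient_proportional <- function(dataset,
                                       fractions = c(tune = 0.08,
                                                     train = 0.72,
                                                     test = 0.20),
                                       seed = 1L,
                                       tune_mode = c("patient", "uniform")) {
  assert_telemonitoring_schema(dataset)
  tune_mode <- match.arg(tune_mode)
  if (!all(c("tune", "train", "test") %in% names(fractions)))
    stop("'fractions' must be named tune/train/test", call. = FALSE)
  fractions <- fractions[c("tune", "train", "test")]
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("'fractions' must be positive and sum to 1", call. = FALSE)
  n <- nrow(dataset)
  subj <- dataset[["subject#"]]
  label <- character(n)
  priority <- c("train", "test", "tune")

  with_local_seed(seed, {
    if (tune_mode == "uniform") {
      n_tune <- round(fractions[["tune"]] * n)
      tune_idx <- sample.int(n, n_tune)
      label[tune_idx] <- "tune"
      rest_frac <- fractions[c("train", "test")] /
        sum(fractions[c("train", "test")])
      for (s in unique(subj)) {
        idx <- setdiff(which(subj == s), tune_idx)
        if (length(idx) == 0L) next
        counts <- largest_remainder(length(idx), rest_frac,
                                    c("train", "test"))
        shuffled <- if (length(idx) > 1L) sample(idx) else idx
        label[shuffled] <- rep(c("train", "test"), counts)
      }
    } else {
      for (s in unique(subj)) {
        idx <- which(subj == s)
        counts <- largest_remainder(length(idx), fractions, priority)
        shuffled <- if (length(idx) > 1L) sample(idx) else idx
        label[shuffled] <- rep(c("tune", "train", "test"), counts)
      }
    }
  })

  structure(list(label = factor(label, levels = c("tune", "train", "test")),
                 fractions = fractions, seed = seed, tune_mode = tune_mode),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("Patient-proportional split (seed ", x$seed, ", tune mode '",
      x$tune_mode, "')\n", sep = "")
  print(table(x$label))
  invisible(x)
}

#' Gender-by-age group labels
#'
#' Partitions patients into the four demographic groups used for the
#' stratified models: 1 = women under the age threshold, 2 = men under it,
#' 3 = women at/above it, 4 = men at/above it.  An age exactly equal to the
#' threshold is placed in the older group.  Sex follows the UCI coding
#' (0 = male, 1 = female).
#'
#' @param dataset a telemonitoring data frame.
#' @param age_threshold age cut point in years (default 65).
#' @return an integer vector of group labels in 1:4, one per recording.
#' @export
assign_groups <- function(dataset, age_threshold = 65) {
  assert_telemonitoring_schema(dataset)
  female <- dataset$sex == 1
  older <- dataset$age >= age_threshold
  ifelse(older, ifelse(female, 3L, 4L), ifelse(female, 1L, 2L))
}

#' Model-ready feature matrix, target, and scaler
#'
#' Extracts the feature matrix and target vector for modeling.  The pooled
#' feature set is the 16 voice measures plus age and sex; `voice_only`
#' drops the demographics (used by the per-group models); `custom` takes an
#' explicit column list (e.g. to include `test_time`).  Standardization
#' (z-scoring) is fitted on the training rows only and applied to all rows;
#' the fitted scaler is returned for reuse on new data.
#'
#' @param dataset a telemonitoring data frame.
#' @param feature_set `"pooled"`, `"voice_only"`, or `"custom"`.
#' @param custom_features character vector of column names when
#'   `feature_set = "custom"`.
#' @param target `"total"` (total UPDRS) or `"motor"`.
#' @param standardize logical; z-score the features.
#' @param train_rows integer indices of the rows used to fit the scaler
#'   (default: all rows).
#' @return a list with `X` (matrix over all rows), `y`, `scaler` (a
#'   `feature_scaler` or `NULL`), and `features`.
#' @export
feature_matrix <- function(dataset,
                           feature_set = c("pooled", "voice_only", "custom"),
                           custom_features = NULL,
                           target = c("total", "motor"),
                           standardize = TRUE, train_rows = NULL) {
  assert_telemonitoring_schema(dataset)
  feature_set <- match.arg(feature_set)
  target <- match.arg(target)
  cols <- switch(feature_set,
    pooled = c(telemonitoring_voice_features(), "age", "sex"),
    voice_only = telemonitoring_voice_features(),
    custom = {
      if (is.null(custom_features))
        stop("'custom_features' required for feature_set = 'custom'",
             call. = FALSE)
      custom_features
    })
  unknown <- setdiff(cols, names(dataset))
  if (length(unknown) > 0L)
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(dataset[cols])
  storage.mode(X) <- "double"
  y <- dataset[[if (target == "total") "total_UPDRS" else "motor_UPDRS"]]
  scaler <- NULL
  if (standardize) {
    scaler <- fit_scaler(X, rows = train_rows)
    X <- scaler_transform(scaler, X)
  }
  list(X = X, y = y, scaler = scaler, features = cols)
}

#' Feature standardization scaler
#'
#' `fit_scaler()` records per-column means and standard deviations
#' (computed on a subset of rows when given); `scaler_transform()` z-scores
#' a matrix with them and `scaler_inverse()` undoes the transform, so that
#' `scaler_transform(s, scaler_inverse(s, x)) == x` up to floating error.
#' Constant columns receive unit scale so they pass through centered.
#'
#' @param X numeric matrix to fit on.
#' @param rows optional row indices used for fitting.
#' @return `fit_scaler()`: a `feature_scaler`; the transforms return
#'   matrices of the input shape.
#' @export
fit_scaler <- function(X, rows = NULL) {
  Xf <- if (is.null(rows)) X else X[rows, , drop = FALSE]
  center <- colMeans(Xf)
  scale <- apply(Xf, 2L, stats::sd)
  scale[!is.finite(scale) | scale <= 0] <- 1
  structure(list(center = center, scale = scale), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler a `feature_scaler`.
#' @export
scaler_transform <- function(scaler, X) {
  stopifnot(inherits(scaler, "feature_scaler"))
  X <- as.matrix(X)
  sweep(sweep(X, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}

#' @rdname fit_scaler
#' @export
scaler_inverse <- function(scaler, X) {
  stopifnot(inherits(scaler, "feature_scaler"))
  X <- as.matrix(X)
  sweep(sweep(X, 2L, scaler$scale, "*"), 2L, scaler$center, "+")
}
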