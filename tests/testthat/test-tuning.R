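fast <- svr_control(check_kernel = FALSE)

# small nonlinear tuning problem reused across blocks
make_tuning_data <- function(seed = 1, n = 60) {
  set.seed(seed)
  X <- matrix(runif(2 * n, -2, 2), n, 2)
  y <- 3 * exp(-2 * rowSums((X - 0.5)^2)) -
    2 * exp(-2 * rowSums((X + 0.8)^2)) + 0.3 * X[, 1] +
    rnorm(n, sd = 0.1)
  list(X = X, y = y)
}

test_that("the default grid enumerates the documented 88 points", {
  grid <- tuning_grid()
  expect_equal(grid$epsilon, seq(0, 1, by = 0.1))
  expect_equal(grid$cost, 2^(2:9))
  dd <- make_tuning_data(1)
  res <- grid_search(dd$X[1:30, ], dd$y[1:30], dd$X[31:60, ], dd$y[31:60],
                     "rbf", control = fast)
  expect_equal(nrow(res$score_table), 88L)
  expect_true(all(res$score_table$converged))
})

test_that("selection matches an exhaustive re-scoring under the tie-break", {
  dd <- make_tuning_data(2)
  res <- grid_search(dd$X[1:30, ], dd$y[1:30], dd$X[31:60, ], dd$y[31:60],
                     "product_mixture",
                     grid = tuning_grid(epsilon = c(0, 0.1, 0.3),
                                        cost = c(4, 16, 64)),
                     control = fast)
  tab <- res$score_table
  best_manual <- tab[order(tab$RMSE, tab$C, tab$epsilon), ][1, ]
  expect_equal(res$best$RMSE, best_manual$RMSE)
  expect_equal(res$best$C, best_manual$C)
  expect_equal(res$best$epsilon, best_manual$epsilon)
  # re-running is deterministic
  res2 <- grid_search(dd$X[1:30, ], dd$y[1:30], dd$X[31:60, ], dd$y[31:60],
                      "product_mixture",
                      grid = tuning_grid(epsilon = c(0, 0.1, 0.3),
                                         cost = c(4, 16, 64)),
                      control = fast)
  expect_identical(res2$score_table, res$score_table)
})

test_that("a single-point grid is returned regardless of its score", {
  dd <- make_tuning_data(3)
  res <- grid_search(dd$X[1:30, ], dd$y[1:30], dd$X[31:60, ], dd$y[31:60],
                     "rbf", grid = tuning_grid(epsilon = 0.9, cost = 4),
                     control = fast)
  expect_equal(nrow(res$score_table), 1L)
  expect_equal(res$best$epsilon, 0.9)
  expect_equal(res$best$C, 4)
})

test_that("select_beta returns the grid argmin of validation RMSE", {
  dd <- make_tuning_data(4)
  one <- select_beta(dd$X[1:30, ], dd$y[1:30], dd$X[31:60, ], dd$y[31:60],
                     beta_values = 0.8, control = fast)
  expect_equal(one$beta, 0.8)
  res <- select_beta(dd$X[1:30, ], dd$y[1:30], dd$X[31:60, ], dd$y[31:60],
                     gamma = 2, epsilon = 0.1, C = 16, control = fast)
  tab <- res$score_table
  expect_equal(res$beta, tab$beta[which.min(tab$RMSE)])
  expect_equal(sort(tab$beta), seq(0.1, 0.9, by = 0.1))
})

test_that("a dominant local component drives beta toward the radial kernel", {
  # fixture: a pure superposition of narrow Gaussian bumps (no global
  # trend), i.e. structure only the local kernel can represent
  wins <- 0L
  for (s in 1:10) {
    set.seed(100 + s)
    X <- matrix(runif(160, -2, 2), 80, 2)
    y <- 3 * exp(-4 * rowSums((X - 0.7)^2)) -
      3 * exp(-4 * rowSums((X + 0.7)^2)) +
      2 * exp(-4 * rowSums(sweep(X, 2, c(-1, 1))^2)) + rnorm(80, sd = 0.05)
    res <- select_beta(X[1:40, ], y[1:40], X[41:80, ], y[41:80],
                       gamma = 4, epsilon = 0.05, C = 32, control = fast)
    if (res$beta >= 0.5) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("per-group tuning fits four internally consistent group models", {
  data <- synth_generate(synth_config(n_patients = 16,
                                      mean_recordings_per_patient = 25,
                                      seed = 71))
  split <- split_patient_proportional(data, seed = 71)
  gf <- tune_per_group(data, split,
                       grid = tuning_grid(epsilon = c(0.1, 0.5),
                                          cost = c(4, 32)),
                       control = fast)
  got_groups <- as.integer(names(gf$groups))
  expect_true(length(got_groups) >= 2L)   # small cohorts may miss a stratum
  for (g in gf$groups) {
    expect_s3_class(g$model, "svr_model")
    expect_equal(ncol(g$model$X), 16L)    # voice-only features
    expect_true(g$tuning$best$converged)
  }
  expect_setequal(unique(gf$metrics$role), c("train", "test"))
  # averages equal the unweighted mean over the reported groups
  tr_rows <- gf$metrics[gf$metrics$role == "train", ]
  expect_equal(gf$average$MAE[gf$average$role == "train"],
               mean(tr_rows$MAE))
  expect_equal(gf$average$RMSE[gf$average$role == "test"],
               mean(gf$metrics$RMSE[gf$metrics$role == "test"]))
})

# cohort whose four gender-by-age strata carry different ground-truth
# feature effects, so pooling mixes heterogeneous relationships
make_grouped_cohort <- function(seed) {
  strata <- list(
    list(age_range = c(45, 60), male = 0, amp = c(9, -6, 8)),
    list(age_range = c(45, 60), male = 1, amp = c(-8, 6, -9)),
    list(age_range = c(68, 84), male = 0, amp = c(7, 8, -8)),
    list(age_range = c(68, 84), male = 1, amp = c(-9, -7, 9)))
  parts <- lapply(seq_along(strata), function(i) {
    st <- strata[[i]]
    cfg <- synth_config(
      n_patients = 8, mean_recordings_per_patient = 25,
      age_range = st$age_range, male_fraction = st$male,
      effect_spec = list(baseline = 25.5, age_slope = 0.3, sex_offset = 3,
                         amp_ppe = st$amp[1], amp_hnr = st$amp[2],
                         amp_interaction = st$amp[3], saturation_rate = 1.2),
      patient_intercept_sd = 3,
      seed = seed * 10 + i)
    d <- synth_generate(cfg)
    d[["subject#"]] <- d[["subject#"]] + (i - 1) * 8
    d
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

test_that("grouped tuning beats a pooled fit under strong group effects", {
  wins <- 0L
  for (s in 1:10) {
    data <- make_grouped_cohort(s)
    pooled <- run_svr_pipeline(data, "product_mixture", seed = s,
                               control = fast)
    gf <- tune_per_group(data, pooled$split, control = fast)
    grouped_rmse <- gf$average$RMSE[gf$average$role == "test"]
    pooled_rmse <- pooled$metrics$RMSE[pooled$metrics$role == "test"]
    if (grouped_rmse < pooled_rmse) wins <- wins + 1L
    # group-wise winning parameters are free to differ across groups
    if (s == 1) {
      pars <- vapply(gf$groups, function(g)
        paste(g$tuning$best$epsilon, g$tuning$best$C), character(1))
      expect_true(length(pars) == 4L)
    }
  }
  expect_gte(wins, 8L)
})
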