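#' Configuration of the synthetic telemonitoring generator
#'
#' Describes a synthetic cohort with the statistical structure of the
#' telemonitoring data: ~42 patients recorded repeatedly over ~6 months,
#' UPDRS assessed at three anchor visits (baseline, 3 and 6 months) and
#' linearly interpolated to the recording times, strongly collinear jitter
#' and shimmer feature blocks, HNR anti-correlated with NHR, and a
#' nonlinear ground-truth relationship between voice features and UPDRS
#' with positive age and male-sex effects.
#'
#' @param n_patients number of patients (default 42, the cohort size).
#' @param mean_recordings_per_patient average recordings per patient
#'   (default 140; recordings are spread over weekly sessions with
#'   repetitions).
#' @param trial_days trial length in days (default 180).
#' @param anchor_days days of the UPDRS anchor assessments, sorted and
#'   starting at 0 (default 0, 90, 180).
#' @param age_range cohort age range in years (default 36-85); ages are
#'   drawn from a normal centred at 65 (sd 9) truncated to this range,
#'   matching the cohort's age distribution.
#' @param male_fraction probability that a patient is male (default 28/42).
#' @param block_correlation target pairwise correlation inside the jitter
#'   (5 features) and shimmer (6 features) blocks, in (-1, 1).
#' @param hnr_noise_correlation target correlation between HNR and NHR
#'   (negative: noisier voices are less harmonic).
#' @param effect_spec list of ground-truth coefficients, see
#'   [synth_ground_truth()]: `baseline`, `age_slope` (UPDRS points per
#'   year), `sex_offset` (male minus female, points), `amp_ppe`, `amp_hnr`
#'   (saturating effect amplitudes, points), `amp_interaction` (PPE x DFA
#'   interaction amplitude, points), `saturation_rate` (slope of the
#'   saturating transform per feature standard deviation).
#' @param patient_intercept_sd standard deviation of the patient-level
#'   UPDRS heterogeneity not explained by the features (points).
#' @param anchor_progression_sd standard deviation of the between-anchor
#'   UPDRS increments (points); the increments have a positive mean so
#'   progression is non-decreasing in expectation.
#' @param anchor_progression_mean mean between-anchor increment (points).
#' @param noise_sd measurement noise on each recording's UPDRS (points).
#' @param within_patient_sd_fraction fraction of each voice feature's
#'   variance attributed to recording-to-recording fluctuation (the rest is
#'   stable patient level).
#' @param seed integer seed; the same configuration and seed always yield
#'   the identical dataset.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 42L,
                         mean_recordings_per_patient = 140,
                         trial_days = 180,
                         anchor_days = c(0, 90, 180),
                         age_range = c(36, 85),
                         male_fraction = 28 / 42,
                         block_correlation = 0.9,
                         hnr_noise_correlation = -0.6,
                         effect_spec = list(baseline = 25.5,
                                            age_slope = 0.3,
                                            sex_offset = 3,
                                            amp_ppe = 4,
                                            amp_hnr = 3,
                                            amp_interaction = 4,
                                            saturation_rate = 1.2),
                         patient_intercept_sd = 5,
                         anchor_progression_mean = 1.5,
                         anchor_progression_sd = 2,
                         noise_sd = 1,
                         within_patient_sd_fraction = 0.3,
                         seed = 1L) {
  stopifnot(n_patients >= 1, mean_recordings_per_patient >= 1,
            trial_days > 0, length(age_range) == 2L,
            age_range[1] < age_range[2])
  if (abs(block_correlation) >= 1 || abs(hnr_noise_correlation) >= 1)
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  if (block_correlation < 0)
    stop("'block_correlation' must be nonnegative for a valid factor ",
         "construction", call. = FALSE)
  if (hnr_noise_correlation > 0)
    stop("'hnr_noise_correlation' must be nonpositive (HNR degrades as ",
         "noise increases)", call. = FALSE)
  anchor_days <- sort(as.numeric(anchor_days))
  if (anchor_days[1] != 0 || length(anchor_days) < 2L)
    stop("'anchor_days' must start at 0 and contain at least two visits",
         call. = FALSE)
  structure(as.list(environment()), class = "synth_config")
}

# target first/second moments of the 16 voice features (cohort-scale
# values; Gaussian marginals truncated at a small positive floor)
synth_voice_moments <- function() {
  data.frame(
    feature = telemonitoring_voice_features(),
    mean = c(0.0062, 4.4e-05, 0.0030, 0.0034, 0.0090,
             0.0340, 0.3100, 0.0170, 0.0200, 0.0280, 0.0520,
             0.0320, 21.68, 0.54, 0.65, 0.22),
    sd = c(0.0056, 3.6e-05, 0.0030, 0.0032, 0.0090,
           0.0260, 0.2300, 0.0130, 0.0170, 0.0200, 0.0400,
           0.0600, 4.29, 0.10, 0.07, 0.09),
    stringsAsFactors = FALSE)
}

#' Noiseless ground-truth UPDRS of the generator
#'
#' Deterministic function mapping demographics and (patient-level) voice
#' features to a total-UPDRS value: an affine part (positive age slope,
#' male offset) plus a smooth nonlinear part in PPE, HNR, and DFA — two
#' saturating (tanh) main effects and a PPE-by-DFA interaction — clipped to
#' the observed score range \[7, 55\].  Setting the three nonlinear
#' amplitudes to zero makes the function exactly affine in age and sex
#' (away from the clipping boundaries).
#'
#' @param config a [synth_config()].
#' @param age age in years.
#' @param sex 0 = male, 1 = female.
#' @param voice named numeric vector (or 1-row data frame) with at least
#'   `PPE`, `HNR`, `DFA`.
#' @return a single noiseless UPDRS value in \[7, 55\].
#' @export
synth_ground_truth <- function(config, age, sex, voice) {
  stopifnot(inherits(config, "synth_config"))
  es <- config$effect_spec
  vm <- synth_voice_moments()
  zs <- function(name, value)
    (value - vm$mean[vm$feature == name]) / vm$sd[vm$feature == name]
  voice <- as.list(voice)
  z_ppe <- zs("PPE", as.numeric(voice$PPE))
  z_hnr <- zs("HNR", as.numeric(voice$HNR))
  z_dfa <- zs("DFA", as.numeric(voice$DFA))
  r <- es$saturation_rate
  value <- es$baseline +
    es$age_slope * (age - 65) +
    es$sex_offset * (sex == 0) +
    es$amp_ppe * tanh(r * z_ppe) -
    es$amp_hnr * tanh(r * z_hnr) +
    es$amp_interaction * z_ppe * z_dfa
  pmin(55, pmax(7, value))
}

#' Generate a synthetic telemonitoring dataset
#'
#' Draws a full cohort under a [synth_config()].  Per patient: a fixed age
#' and sex; stable voice-feature levels built from a factor model that
#' induces the configured within-block correlations (jitter block, shimmer
#' block) and the negative HNR-NHR correlation; roughly weekly recording
#' sessions with repetitions and small day jitter across the trial; three
#' anchor UPDRS values equal to the ground truth plus a patient intercept
#' and non-decreasing-in-expectation increments; per-recording total UPDRS
#' linearly interpolated between the surrounding anchors plus measurement
#' noise.  Motor UPDRS is an affine transform of total UPDRS plus noise,
#' emitted only for schema fidelity.
#'
#' @param config a [synth_config()].
#' @return a data frame in the canonical CSV schema (see
#'   [telemonitoring_columns()]).  Attributes `patients` (per-patient age,
#'   sex, intercept) and `anchors` (per-patient anchor UPDRS values and
#'   days, plus each recording's noiseless interpolated value in attribute
#'   `noiseless`) support testing of the interpolation structure.
#' @export
synth_generate <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  vm <- synth_voice_moments()
  feats <- vm$feature
  jitter_block <- feats[1:5]
  shimmer_block <- feats[6:11]
  rho <- config$block_correlation
  rho_hn <- -config$hnr_noise_correlation   # magnitude of the shared factor
  wthn <- config$within_patient_sd_fraction

  with_local_seed(config$seed, {
    n_pat <- config$n_patients
    age <- pmin(config$age_range[2],
                pmax(config$age_range[1], stats::rnorm(n_pat, 65, 9)))
    sex <- ifelse(stats::runif(n_pat) < config$male_fraction, 0L, 1L)
    intercept <- stats::rnorm(n_pat, 0, config$patient_intercept_sd)

    # latent standard-normal feature scores with the target correlations,
    # split into a stable patient level and per-recording fluctuation
    draw_scores <- function(m) {
      z <- matrix(stats::rnorm(m * length(feats)), m, length(feats),
                  dimnames = list(NULL, feats))
      f_jit <- stats::rnorm(m); f_shim <- stats::rnorm(m)
      g <- stats::rnorm(m)
      z[, jitter_block] <- sqrt(rho) * f_jit +
        sqrt(1 - rho) * z[, jitter_block]
      z[, shimmer_block] <- sqrt(rho) * f_shim +
        sqrt(1 - rho) * z[, shimmer_block]
      z[, "NHR"] <- sqrt(rho_hn) * g + sqrt(1 - rho_hn) * z[, "NHR"]
      z[, "HNR"] <- -sqrt(rho_hn) * g + sqrt(1 - rho_hn) * z[, "HNR"]
      z
    }
    patient_z <- draw_scores(n_pat)

    rows <- vector("list", n_pat)
    pat_anchor <- vector("list", n_pat)
    weeks <- seq(0, floor(config$trial_days / 7))
    for (j in seq_len(n_pat)) {
      n_rec <- max(2L, round(config$mean_recordings_per_patient *
                               stats::runif(1, 0.7, 1.3)))
      wk <- sort(sample(weeks, n_rec, replace = TRUE))
      tt <- 7 * wk + stats::runif(n_rec, -1.5, 1.5)
      tt <- pmin(config$trial_days, tt)   # may dip slightly below 0 at week 0

      z <- sqrt(1 - wthn) * matrix(patient_z[j, ], n_rec, length(feats),
                                   byrow = TRUE) +
        sqrt(wthn) * draw_scores(n_rec)
      V <- sweep(sweep(z, 2L, vm$sd, "*"), 2L, vm$mean, "+")
      V[] <- pmax(V, 1e-7)          # voice measures are nonnegative
      V[, "HNR"] <- pmax(V[, "HNR"], 1)

      pat_voice <- stats::setNames(vm$mean + vm$sd * patient_z[j, ], feats)
      base <- synth_ground_truth(config, age[j], sex[j], pat_voice) +
        intercept[j]
      inc <- stats::rnorm(length(config$anchor_days) - 1L,
                          config$anchor_progression_mean,
                          config$anchor_progression_sd)
      anchors <- pmin(55, pmax(7, cumsum(c(base, inc))))
      noiseless <- stats::approx(config$anchor_days, anchors,
                                 xout = pmax(0, pmin(tt, config$trial_days)),
                                 rule = 2)$y
      total <- noiseless + stats::rnorm(n_rec, 0, config$noise_sd)
      motor <- pmin(40, pmax(5, 0.7 * total - 5 + stats::rnorm(n_rec, 0, 1)))

      df <- data.frame(j, age[j], sex[j], tt, motor, total,
                       check.names = FALSE, stringsAsFactors = FALSE)
      names(df) <- c("subject#", "age", "sex", "test_time",
                     "motor_UPDRS", "total_UPDRS")
      df <- cbind(df, as.data.frame(V, optional = TRUE))
      names(df) <- telemonitoring_columns()
      attr(df, "noiseless") <- noiseless
      rows[[j]] <- df
      pat_anchor[[j]] <- anchors
    }

    noiseless <- unlist(lapply(rows, attr, "noiseless"))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "patients") <- data.frame(subject = seq_len(n_pat), age = age,
                                        sex = sex, intercept = intercept)
    attr(out, "anchors") <- list(days = config$anchor_days,
                                 values = do.call(rbind, pat_anchor),
                                 noiseless = noiseless)
    out
  })
}
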