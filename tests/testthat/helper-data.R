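# hand-constructed telemonitoring data frame in the canonical schema;
# `subjects` is a named list: subject id -> number of recordings
make_schema_df <- function(subjects = list(`1` = 3), age = 60, sex = 0,
                           voice_value = 0.1, updrs = 20) {
  rows <- lapply(names(subjects), function(s) {
    n <- subjects[[s]]
    df <- data.frame(as.numeric(s),
                     if (length(age) > 1) age[[s]] else age,
                     if (length(sex) > 1) sex[[s]] else sex,
                     seq_len(n) * 7 - 3.5,
                     updrs * 0.7, updrs,
                     check.names = FALSE)
    voice <- matrix(voice_value, n, 16)
    df <- cbind(df, as.data.frame(voice))
    names(df) <- telemonitoring_columns()
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

small_cohort <- function(seed = 1, n_patients = 8, recs = 20) {
  synth_generate(synth_config(n_patients = n_patients,
                              mean_recordings_per_patient = recs,
                              seed = seed))
}
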