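# small hand-built cohorts used across test files

make_test_records <- function(n = 3) {
  data.frame(
    patient_id = sprintf("p%03d", seq_len(n)),
    cohort = rep(c("trauma", "general"), length.out = n),
    age = seq(20, by = 11, length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    admission_type = rep(c("emergency", "elective"), length.out = n),
    los_days = seq_len(n),
    ed_visits_6mo = rep(0:1, length.out = n),
    history_text = rep(c("known DM, on treatment", ""), length.out = n),
    outcome = rep(c("unplanned_readmission", "other"), length.out = n),
    stringsAsFactors = FALSE)
}

write_test_csv <- function(d, path = tempfile(fileext = ".csv")) {
  utils::write.csv(d, path, row.names = FALSE)
  path
}
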