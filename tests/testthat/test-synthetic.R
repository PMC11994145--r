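dict <- build_default_dictionary()

test_that("generation is deterministic under a fixed seed and valid at n = 1", {
  prof <- cohort_profile("trauma", n = 200)
  a <- generate_cohort(prof, seed = 9, dictionary = dict)
  b <- generate_cohort(prof, seed = 9, dictionary = dict)
  expect_identical(a, b)
  c_ <- generate_cohort(prof, seed = 10, dictionary = dict)
  expect_false(identical(a$history_text, c_$history_text))

  one <- generate_cohort(cohort_profile("general", n = 1), seed = 3,
                         dictionary = dict)
  expect_equal(nrow(one), 1)
  expect_silent(validate_records(one))
})

test_that("planted-term recovery: extraction equals gold on template histories", {
  canon <- dictionary_conditions(dict)$canonical
  set.seed(101)
  hits <- vapply(1:1000, function(i) {
    conds <- sample(canon, sample(0:4, 1))
    txt <- generate_history_text(conds, dict, n_filler = sample(1:3, 1))
    gold <- lacescore:::score_condition_set(conds, dict)
    got <- charlson_score(data.frame(history_text = txt, age = 30), dict)
    got == gold
  }, logical(1))
  expect_equal(mean(hits), 1.0)
  expect_error(generate_history_text("not_a_condition", dict), "unknown")
  # empty set: filler only, zero score
  set.seed(102)
  txt0 <- generate_history_text(character(0), dict)
  expect_equal(charlson_score(data.frame(history_text = txt0, age = 20),
                              dict), 0L)
})

test_that("reordering whole planted phrases leaves the score unchanged", {
  set.seed(103)
  canon <- dictionary_conditions(dict)$canonical
  for (i in 1:50) {
    conds <- sample(canon, sample(1:4, 1))
    t1 <- generate_history_text(conds, dict)
    t2 <- generate_history_text(rev(conds), dict)
    s1 <- charlson_score(data.frame(history_text = t1, age = 45), dict)
    s2 <- charlson_score(data.frame(history_text = t2, age = 45), dict)
    expect_equal(s1, s2)
  }
})

test_that("the distractor vocabulary contains no dictionary surface form", {
  fillers <- lacescore:::.filler_sentences
  openers <- lacescore:::.phrase_openers
  obf <- lacescore:::.obfuscated_phrases
  # individually and across sentence joins, filler text must score zero
  combos <- c(fillers, obf,
              as.vector(outer(fillers, fillers, paste, sep = ". ")),
              as.vector(outer(openers, fillers, paste)))
  scores <- charlson_score(data.frame(history_text = combos, age = 20), dict)
  expect_true(all(scores == 0L))
})

test_that("intercept calibration hits the target prevalence", {
  # closed forms at slope zero
  expect_equal(calibrate_intercept(rep(0, 50), 0.5), 0, tolerance = 1e-8)
  expect_equal(calibrate_intercept(rep(0, 50), 0.2), qlogis(0.2),
               tolerance = 1e-6)
  set.seed(104)
  eta <- 0.15 * sample(0:19, 500, replace = TRUE)
  a <- calibrate_intercept(eta, 2192 / 19120)
  expect_equal(mean(plogis(a + eta)), 2192 / 19120, tolerance = 1e-6)
})

test_that("built-in profiles reproduce the printed cohort structure", {
  prof <- cohort_profile("general", n = 6000)
  rec <- generate_cohort(prof, seed = 11, dictionary = dict)
  n <- nrow(rec)
  se_mean <- function(x) sd(x) / sqrt(n)
  expect_lt(abs(mean(rec$age) - 49.33), 3 * se_mean(rec$age) + 0.05)
  expect_lt(abs(sd(rec$age) - 17.44), 0.8)
  expect_lt(abs(mean(rec$sex == "male") - 0.47), 3 * sqrt(0.47 * 0.53 / n))
  expect_lt(abs(mean(rec$admission_type == "emergency") - 0.49),
            3 * sqrt(0.49 * 0.51 / n))
  expect_lt(abs(mean(rec$los_days) - 3.04), 3 * se_mean(rec$los_days))
  text_cci <- rec$gold_cci - age_points(rec$age)
  expect_lt(abs(mean(text_cci) - 1.56), 3 * se_mean(text_cci))
  prev <- mean(rec$outcome == "unplanned_readmission")
  p0 <- 2192 / 19120
  expect_lt(abs(prev - p0), 3 * sqrt(p0 * (1 - p0) / n))

  tra <- generate_cohort(cohort_profile("trauma", n = 6000), seed = 12,
                         dictionary = dict)
  expect_lt(abs(mean(tra$age) - 33.91), 3 * se_mean(tra$age) + 0.05)
  expect_lt(abs(mean(tra$sex == "male") - 0.85), 3 * sqrt(0.85 * 0.15 / n))
  expect_lt(abs(mean(tra$gold_cci - age_points(tra$age)) - 0.2), 0.05)
})

test_that("obfuscation lowers machine-gold concordance; default is exact", {
  prof <- cohort_profile("general", n = 600, obfuscation_rate = 0.3)
  rec <- generate_cohort(prof, seed = 13, dictionary = dict)
  got <- charlson_score(rec, dict)
  conc <- concordance(got, rec$gold_cci)
  expect_lt(conc, 1.0)
  expect_gt(conc, 0.5)
  expect_true(all(got <= rec$gold_cci))
})

test_that("infeasible prevalence targets error instead of silently clipping", {
  expect_error(cohort_profile("general", target_prevalence = 0), "target_prevalence")
})
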