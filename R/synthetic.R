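#' @title Synthetic admission cohorts
#' @description Seeded generator of admission cohorts whose structure matches
#'   the two study populations (trauma and general surgery), including
#'   free-text histories with planted dictionary terms and a stored gold
#'   comorbidity score, so every pipeline stage can be checked against known
#'   ground truth.
#' @name synthetic_cohort
NULL

# base mix over canonical conditions (relative prevalence of each comorbidity
# among planted conditions); scaled per profile to hit the target mean
# condition-weight score
.condition_mix <- c(
  diabetes = 0.235, coronary_artery_disease = 0.115, heart_failure = 0.08,
  chronic_pulmonary_disease = 0.10, cerebrovascular_disease = 0.08,
  myocardial_infarction = 0.05, peripheral_vascular_disease = 0.05,
  dementia = 0.03, peptic_ulcer_disease = 0.04, mild_liver_disease = 0.06,
  renal_disease = 0.06, malignancy = 0.05, leukemia = 0.01,
  moderate_severe_liver_disease = 0.015, metastatic_solid_tumor = 0.02,
  aids = 0.015)

# frozen distractor vocabulary: clinical-style filler containing no
# dictionary surface form (screened by the test suite)
.filler_sentences <- c(
  "patient stable on arrival", "no acute distress noted",
  "vital signs within normal limits", "seen at local clinic last month",
  "tolerating oral intake", "ambulating independently",
  "follow up arranged at outpatient department", "wound clean and dry",
  "analgesia charted as required", "social circumstances reviewed",
  "no known drug allergies", "immunisations up to date",
  "lives with family nearby", "non-smoker", "occasional alcohol use",
  "awaiting physiotherapy review")

.phrase_openers <- c("known", "history of", "background of", "longstanding",
                     "previous", "reports")

# mean and sd of a normal(m, s) truncated to [lo, hi]
.trunc_norm_moments <- function(m, s, lo, hi) {
  a <- (lo - m) / s; b <- (hi - m) / s
  z <- stats::pnorm(b) - stats::pnorm(a)
  dn <- (stats::dnorm(a) - stats::dnorm(b)) / z
  tm <- m + s * dn
  tv <- s^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / z - dn^2)
  c(mean = tm, sd = sqrt(tv))
}

# parent normal parameters whose truncation to [lo, hi] has the target
# observed mean and sd (deterministic Nelder-Mead solve)
.solve_trunc_normal <- function(target_mean, target_sd, lo = 18, hi = 100) {
  obj <- function(par) {
    mo <- .trunc_norm_moments(par[1], exp(par[2]), lo, hi)
    (mo["mean"] - target_mean)^2 + (mo["sd"] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mean = fit$par[1], sd = exp(fit$par[2]))
}

# deliberately unmatched severity phrasing used by the obfuscation option
.obfuscated_phrases <- c("long term sugar problem", "weak heart per family",
                         "breathing trouble for years", "growth under review")

#' Cohort generation profile
#'
#' Bundles the population parameters of a synthetic admission cohort. The two
#' built-in profiles reproduce the printed structure of the study cohorts:
#' `"trauma"` (n = 12,590; unplanned prevalence 804/12,590; age 33.91 +/-
#' 12.26 truncated to 18-100; 85% male; 95% emergency; length of stay
#' negative-binomial with mean 1.76, SD 2.18; mean text comorbidity score
#' 0.2; true LACE log-odds slope 0.11 with sex covariate slope 0.52) and
#' `"general"` (n = 19,120; prevalence 2,192/19,120; age 49.33 +/- 17.44; 47%
#' male; 49% emergency; LOS mean 3.04, SD 2.08; mean text comorbidity score
#' 1.56; LACE slope 0.15 with age covariate slope -0.004). ED visit rates are
#' not printed for the study cohorts; the defaults (0.35 and 0.45 visits per
#' 6 months) place the cohort mean LACE near the printed totals.
#'
#' @param profile `"trauma"`, `"general"` or `"custom"`.
#' @param ... Overrides of any profile field: `n`, `target_prevalence`,
#'   `age_mean`, `age_sd`, `prop_male`, `prop_emergency`, `los_mean`,
#'   `los_sd`, `ed_visit_rate`, `cci_text_mean` (target mean planted
#'   condition-weight score), `lace_slope`, `covariate` (`"sex"`, `"age"` or
#'   `"none"`), `covariate_slope`, `obfuscation_rate`, `cohort` (label),
#'   `seed`.
#' @return A `cohort_profile` list.
#' @export
cohort_profile <- function(profile = c("trauma", "general", "custom"), ...) {
  name <- match.arg(profile)
  base <- switch(name,
    trauma = list(n = 12590L, target_prevalence = 804 / 12590,
                  age_mean = 33.91, age_sd = 12.26, prop_male = 0.85,
                  prop_emergency = 0.95, los_mean = 1.76, los_sd = 2.18,
                  ed_visit_rate = 0.35, cci_text_mean = 0.2,
                  lace_slope = 0.11, covariate = "sex",
                  covariate_slope = 0.52, cohort = "trauma"),
    general = list(n = 19120L, target_prevalence = 2192 / 19120,
                   age_mean = 49.33, age_sd = 17.44, prop_male = 0.47,
                   prop_emergency = 0.49, los_mean = 3.04, los_sd = 2.08,
                   ed_visit_rate = 0.45, cci_text_mean = 1.56,
                   lace_slope = 0.15, covariate = "age",
                   covariate_slope = -0.004, cohort = "general"),
    custom = list(n = 1000L, target_prevalence = 0.1,
                  age_mean = 45, age_sd = 15, prop_male = 0.5,
                  prop_emergency = 0.5, los_mean = 2.5, los_sd = 2.5,
                  ed_visit_rate = 0.4, cci_text_mean = 1,
                  lace_slope = 0.1, covariate = "none",
                  covariate_slope = 0, cohort = "general"))
  base$name <- name
  base$obfuscation_rate <- 0
  base$seed <- 1L
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown) > 0L)
    stop("unknown profile field(s): ", paste(unknown, collapse = ", "))
  p <- utils::modifyList(base, overrides)
  stopifnot(p$n >= 1, p$target_prevalence > 0, p$target_prevalence < 1,
            p$prop_male >= 0, p$prop_male <= 1,
            p$prop_emergency >= 0, p$prop_emergency <= 1,
            p$los_mean >= 0, p$ed_visit_rate >= 0, p$cci_text_mean >= 0,
            p$obfuscation_rate >= 0, p$obfuscation_rate <= 1,
            p$covariate %in% c("sex", "age", "none"),
            p$cohort %in% c("trauma", "general"))
  structure(p, class = "cohort_profile")
}

# per-condition planting probabilities: presence is independent Bernoulli
# r * mix_c; r solves E[score] = r*sum(q w) - r^2 * (dominance overlap loss)
# exactly for the target mean condition-weight score
.condition_probs <- function(target_mean, dictionary) {
  q <- .condition_mix / sum(.condition_mix)
  canon <- dictionary_conditions(dictionary)
  w <- canon$weight[match(names(q), canon$canonical)]
  a <- sum(q * w)
  b <- q[["mild_liver_disease"]] * q[["moderate_severe_liver_disease"]] * 1 +
       q[["malignancy"]] * q[["metastatic_solid_tumor"]] * 2
  r <- if (b > 0) (a - sqrt(a^2 - 4 * b * target_mean)) / (2 * b)
       else target_mean / a
  p <- pmin(r * q, 0.95)
  p
}

#' Build a clinical-style history text around planted conditions
#'
#' Each planted condition contributes one randomly chosen surface form,
#' wrapped in a short opener; neutral filler sentences from a frozen
#' distractor list (screened to contain no dictionary surface form) are mixed
#' in and the sentence order is shuffled. By construction,
#' [charlson_score()] on the output recovers exactly the planted weights.
#'
#' @param conditions Character vector of canonical condition names (may be
#'   empty).
#' @param dictionary A `lace_dictionary`.
#' @param n_filler Number of filler sentences.
#' @param obfuscate If TRUE, one planted condition phrase is replaced by a
#'   deliberately unmatched severity paraphrase (used to emulate
#'   machine-versus-expert scoring discrepancies); the text then under-scores
#'   relative to the planted gold.
#' @return A single character string. Uses the current RNG state.
#' @export
generate_history_text <- function(conditions, dictionary = build_default_dictionary(),
                                  n_filler = 2L, obfuscate = FALSE) {
  canon <- dictionary_conditions(dictionary)
  if (!all(conditions %in% canon$canonical))
    stop("unknown condition(s): ",
         paste(setdiff(conditions, canon$canonical), collapse = ", "))
  phrases <- vapply(conditions, function(cc) {
    forms <- dictionary$phrase[dictionary$canonical == cc]
    forms[sample.int(length(forms), 1L)]
  }, character(1))
  if (obfuscate && length(phrases) > 0L) {
    i <- sample.int(length(phrases), 1L)
    phrases[i] <- .obfuscated_phrases[sample.int(length(.obfuscated_phrases), 1L)]
  }
  sentences <- c(
    if (length(phrases) > 0L)
      paste(.phrase_openers[sample.int(length(.phrase_openers),
                                       length(phrases), replace = TRUE)],
            phrases),
    .filler_sentences[sample.int(length(.filler_sentences),
                                 min(n_filler, length(.filler_sentences)))])
  sentences <- sentences[sample.int(length(sentences))]
  paste0(paste(sentences, collapse = ". "), ".")
}

#' Calibrate the outcome-model intercept to a target prevalence
#'
#' Bisection on the intercept `alpha` so that the cohort-average readmission
#' probability `mean(plogis(alpha + eta))` hits the target prevalence to
#' within `tol`; the bracket is widened automatically before giving up.
#'
#' @param eta Numeric vector of linear-predictor offsets (slope x LACE plus
#'   any covariate term), non-degenerate.
#' @param target Target prevalence in (0, 1).
#' @param tol Calibration tolerance on the achieved mean probability.
#' @return The intercept `alpha`.
#' @export
calibrate_intercept <- function(eta, target, tol = 1e-6) {
  stopifnot(length(eta) >= 1, target > 0, target < 1)
  f <- function(a) mean(stats::plogis(a + eta)) - target
  lo <- -20; hi <- 20
  for (w in 1:4) {
    if (f(lo) < 0 && f(hi) > 0) break
    lo <- lo * 2; hi <- hi * 2
  }
  if (!(f(lo) < 0 && f(hi) > 0))
    stop("infeasible prevalence: no intercept reaches target ", target)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol * 1e-3 || (hi - lo) < 1e-12) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
  mid
}

#' Generate a seeded synthetic admission cohort
#'
#' Draws demographics, admission characteristics and planted comorbidity
#' sets from the profile's distributions (age: truncated normal on
#' \[18, 100\]; length of stay: negative binomial; ED visits: Poisson;
#' conditions: independent Bernoulli per dictionary category, calibrated so
#' the expected condition-weight score equals `cci_text_mean`), builds each
#' history text with [generate_history_text()], stores the planted gold score
#' (`gold_cci` = retained condition weights + age points), and draws the
#' outcome as Bernoulli(plogis(alpha + lace_slope x LACE + covariate term))
#' with the LACE total computed through the package's scoring chain and
#' `alpha` from [calibrate_intercept()]. Fully reproducible for a given seed.
#'
#' @param profile A `cohort_profile`.
#' @param seed Integer seed (defaults to the profile's).
#' @param dictionary A `lace_dictionary`.
#' @param ed_mode LACE E-component mode used for the outcome model.
#' @return Record data frame with `gold_cci`; attributes `alpha`, `seed`,
#'   `profile`.
#' @export
generate_cohort <- function(profile, seed = profile$seed,
                            dictionary = build_default_dictionary(),
                            ed_mode = "binary") {
  stopifnot(inherits(profile, "cohort_profile"))
  set.seed(as.integer(seed))
  n <- as.integer(profile$n)
  # profile age_mean/age_sd describe the observed (truncated) cohort; draw
  # from the parent normal whose [18, 100] truncation has those moments
  ap <- .solve_trunc_normal(profile$age_mean, profile$age_sd)
  u <- stats::runif(n, stats::pnorm(18, ap["mean"], ap["sd"]),
                    stats::pnorm(100, ap["mean"], ap["sd"]))
  age <- round(stats::qnorm(u, ap["mean"], ap["sd"]), 1)
  age <- pmin(pmax(age, 18), 100)
  sex <- ifelse(stats::runif(n) < profile$prop_male, "male", "female")
  admission_type <- ifelse(stats::runif(n) < profile$prop_emergency,
                           "emergency", "elective")
  los_var <- profile$los_sd^2
  los <- if (los_var > profile$los_mean) {
    size <- profile$los_mean^2 / (los_var - profile$los_mean)
    stats::rnbinom(n, size = size, mu = profile$los_mean)
  } else {
    stats::rpois(n, profile$los_mean)
  }
  ed <- stats::rpois(n, profile$ed_visit_rate)

  canon <- dictionary_conditions(dictionary)
  probs <- .condition_probs(profile$cci_text_mean, dictionary)
  probs <- probs[canon$canonical]
  cond_mat <- matrix(stats::runif(n * nrow(canon)), nrow = n) <
    matrix(probs, nrow = n, ncol = nrow(canon), byrow = TRUE)
  colnames(cond_mat) <- canon$canonical
  obf <- stats::runif(n) < profile$obfuscation_rate
  history <- vapply(seq_len(n), function(i) {
    generate_history_text(canon$canonical[cond_mat[i, ]], dictionary,
                          n_filler = 2L, obfuscate = obf[i])
  }, character(1))
  gold_text <- as.integer(.apply_dominance(cond_mat, canon) %*% canon$weight)
  gold_cci <- gold_text + age_points(age)

  records <- data.frame(
    patient_id = sprintf("%s-%06d", profile$cohort, seq_len(n)),
    cohort = profile$cohort, age = age, sex = sex,
    admission_type = admission_type, los_days = as.integer(los),
    ed_visits_6mo = as.integer(ed), history_text = history,
    outcome = "other", gold_cci = gold_cci, stringsAsFactors = FALSE)

  lace <- lace_score(records, gold_cci, ed_mode = ed_mode)
  cov_term <- switch(profile$covariate,
                     sex = profile$covariate_slope * (sex == "male"),
                     age = profile$covariate_slope * age,
                     none = 0)
  eta <- profile$lace_slope * lace$lace_total + cov_term
  alpha <- calibrate_intercept(eta, profile$target_prevalence)
  p <- stats::plogis(alpha + eta)
  records$outcome <- ifelse(stats::runif(n) < p, "unplanned_readmission",
                            "other")
  attr(records, "alpha") <- alpha
  attr(records, "seed") <- as.integer(seed)
  attr(records, "profile") <- profile
  records
}
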