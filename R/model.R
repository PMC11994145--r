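#' @title Logistic readmission models
#' @description Logistic regression of unplanned readmission on the LACE
#'   total plus one covariate, reported as odds ratios with Wald intervals.
#' @name readmission_models
NULL

#' Fit a logistic regression of a binary outcome on named predictors
#'
#' Maximum-likelihood fit by iteratively reweighted least squares (Fisher
#' scoring via [stats::glm()], relative-deviance tolerance 1e-10, at most 50
#' iterations) with an intercept added automatically. Standard errors are
#' Wald (inverse observed information); odds ratios are `exp(beta)` with 95%
#' intervals `exp(beta +/- z_{0.975} * SE)` on the log-odds scale.
#'
#' @param predictors Data frame (or matrix) of finite numeric columns.
#' @param outcome Binary vector (logical or 0/1) with both classes present.
#' @return A `logistic_fit`: term names, `beta`, `se`, `z`, `p`, `or_`,
#'   `or_ci` (matrix with `lower`/`upper`), `converged`, `n_iterations`,
#'   `log_likelihood`, `n`.
#' @examples
#' set.seed(1)
#' x <- data.frame(score = rnorm(200))
#' y <- rbinom(200, 1, plogis(-1 + 0.8 * x$score))
#' fit_logistic(x, y)
#' @export
fit_logistic <- function(predictors, outcome) {
  predictors <- as.data.frame(predictors)
  y <- as.numeric(as.logical(outcome))
  if (anyNA(y)) stop("outcome must be binary (logical or 0/1)")
  if (length(y) != nrow(predictors)) stop("outcome/predictor length mismatch")
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; cannot fit")
  if (!all(vapply(predictors, function(c) all(is.finite(c)), logical(1))))
    stop("predictor columns must be finite")
  const <- vapply(predictors, function(c) stats::var(c) == 0, logical(1))
  if (any(const))
    stop("zero-variance predictor: ",
         paste(names(predictors)[const], collapse = ", "))
  dat <- cbind(predictors, .y = y)
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10, maxit = 50))
  coefs <- summary(fit)$coefficients
  beta <- coefs[, "Estimate"]
  se <- coefs[, "Std. Error"]
  if (!fit$converged || any(se > 100)) {
    worst <- rownames(coefs)[which.max(se)]
    stop("model did not converge (possible quasi-separation in term ",
         worst, ")")
  }
  zq <- stats::qnorm(0.975)
  ci <- cbind(lower = exp(beta - zq * se), upper = exp(beta + zq * se))
  structure(list(terms = rownames(coefs),
                 beta = unname(beta), se = unname(se),
                 z = unname(coefs[, "z value"]),
                 p = unname(coefs[, "Pr(>|z|)"]),
                 or_ = unname(exp(beta)),
                 or_ci = unname(ci),
                 converged = fit$converged,
                 n_iterations = fit$iter,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 n = length(y),
                 glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic fit (n = %d, logLik = %.2f, %d IRLS iterations)\n",
              x$n, x$log_likelihood, x$n_iterations))
  tab <- data.frame(term = x$terms,
                    beta = round(x$beta, digits),
                    se = round(x$se, digits),
                    z = round(x$z, 2),
                    p = signif(x$p, 3),
                    OR = round(x$or_, 3),
                    ci_low = round(x$or_ci[, 1], 3),
                    ci_high = round(x$or_ci[, 2], 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Coefficient table of a logistic fit
#'
#' @param fit A `logistic_fit`.
#' @return Data frame with one row per term: `term`, `beta`, `se`, `z`, `p`,
#'   `or`, `or_low`, `or_high`.
#' @export
coef_table <- function(fit) {
  data.frame(term = fit$terms, beta = fit$beta, se = fit$se, z = fit$z,
             p = fit$p, or = fit$or_, or_low = fit$or_ci[, 1],
             or_high = fit$or_ci[, 2], stringsAsFactors = FALSE)
}

#' Fit the per-cohort readmission models
#'
#' Trauma model: unplanned readmission ~ LACE total + sex (male = 1,
#' female = 0; records with unknown sex are dropped and counted). General
#' surgery model: unplanned readmission ~ LACE total + age. Cohorts absent
#' from the data are skipped.
#'
#' @param records Record data frame (may mix cohorts).
#' @param scores Aligned data frame from [lace_score()].
#' @return Named list of `logistic_fit` objects (by cohort); each carries an
#'   attribute `n_dropped` with the count of records excluded for a missing
#'   covariate.
#' @export
fit_cohort_models <- function(records, scores) {
  if (nrow(records) != nrow(scores)) stop("records and scores are misaligned")
  out <- list()
  for (ch in intersect(c("trauma", "general"), unique(records$cohort))) {
    idx <- records$cohort == ch
    r <- records[idx, , drop = FALSE]
    s <- scores[idx, , drop = FALSE]
    y <- r$outcome == "unplanned_readmission"
    if (ch == "trauma") {
      keep <- r$sex != "unknown"
      pred <- data.frame(lace = s$lace_total[keep],
                         sex_male = as.numeric(r$sex[keep] == "male"))
      fit <- fit_logistic(pred, y[keep])
      attr(fit, "n_dropped") <- sum(!keep)
    } else {
      pred <- data.frame(lace = s$lace_total, age = r$age)
      fit <- fit_logistic(pred, y)
      attr(fit, "n_dropped") <- 0L
    }
    out[[ch]] <- fit
  }
  if (length(out) == 0L) stop("no trauma or general cohort records found")
  out
}
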