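#' @title Screening evaluation and group comparisons
#' @description Confusion matrix of the high-risk flag against unplanned
#'   readmission, screening metrics with exact binomial accuracy intervals,
#'   and the Welch t / Yates chi-square group comparisons of the cohort
#'   characteristic tables.
#' @name evaluation
NULL

#' Confusion matrix of a binary flag against a binary outcome
#'
#' Positive class = unplanned readmission; flagged = LACE total at or above
#' the threshold.
#'
#' @param flags Logical vector (or 0/1) of high-risk flags.
#' @param outcomes Logical vector (or 0/1), TRUE for unplanned readmission.
#' @return A `confusion_matrix`: list with integer counts `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_matrix <- function(flags, outcomes) {
  if (length(flags) != length(outcomes))
    stop("flags and outcomes must have equal length")
  if (length(flags) == 0L) stop("empty input")
  f <- as.logical(flags); o <- as.logical(outcomes)
  if (anyNA(f) || anyNA(o)) stop("flags and outcomes must be non-missing")
  structure(list(tp = sum(f & o), fp = sum(f & !o),
                 fn = sum(!f & o), tn = sum(!f & !o)),
            class = "confusion_matrix")
}

#' Build a confusion matrix from its four counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return A `confusion_matrix`.
#' @export
as_confusion_matrix <- function(tp, fp, fn, tn) {
  if (any(c(tp, fp, fn, tn) < 0)) stop("counts must be non-negative")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("          outcome+  outcome-\n")
  cat(sprintf("flagged   %8d  %8d\n", x$tp, x$fp))
  cat(sprintf("unflagged %8d  %8d\n", x$fn, x$tn))
  invisible(x)
}

.safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator)")
    return(NA_real_)
  }
  num / den
}

#' Screening metrics of a confusion matrix
#'
#' Sensitivity, specificity, positive and negative predictive value, accuracy
#' with an exact (Clopper-Pearson) binomial confidence interval, prevalence,
#' the no-information rate (majority-class proportion) and the flagged rate.
#' A metric with a zero denominator is reported as `NA` with a warning rather
#' than coerced to 0.
#'
#' @param cm A `confusion_matrix`.
#' @param conf_level Confidence level of the accuracy interval (default 0.95).
#' @return A `classification_metrics` list.
#' @examples
#' cm <- as_confusion_matrix(tp = 111, fp = 987, fn = 693, tn = 10799)
#' classification_metrics(cm)
#' @export
classification_metrics <- function(cm, conf_level = 0.95) {
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  if (n < 1L) stop("empty confusion matrix")
  prev <- (cm$tp + cm$fn) / n
  acc_test <- stats::binom.test(cm$tp + cm$tn, n, conf.level = conf_level)
  structure(list(
    sensitivity = .safe_ratio(cm$tp, cm$tp + cm$fn, "sensitivity"),
    specificity = .safe_ratio(cm$tn, cm$tn + cm$fp, "specificity"),
    ppv = .safe_ratio(cm$tp, cm$tp + cm$fp, "ppv"),
    npv = .safe_ratio(cm$tn, cm$tn + cm$fn, "npv"),
    accuracy = (cm$tp + cm$tn) / n,
    accuracy_ci = as.numeric(acc_test$conf.int),
    prevalence = prev,
    nir = max(prev, 1 - prev),
    flagged_rate = (cm$tp + cm$fp) / n,
    n = as.integer(n)), class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  pct <- function(v) ifelse(is.na(v), "   NA", sprintf("%5.2f%%", 100 * v))
  cat(sprintf("n = %d, prevalence = %s, flagged = %s, NIR = %s\n",
              x$n, pct(x$prevalence), pct(x$flagged_rate), pct(x$nir)))
  cat(sprintf("sensitivity %s  specificity %s\n",
              pct(x$sensitivity), pct(x$specificity)))
  cat(sprintf("PPV %s  NPV %s\n", pct(x$ppv), pct(x$npv)))
  cat(sprintf("accuracy %s (95%% CI %s, %s)\n", pct(x$accuracy),
              pct(x$accuracy_ci[1]), pct(x$accuracy_ci[2])))
  invisible(x)
}

#' Group summary (n, mean, SD)
#'
#' @param n Group size (>= 2).
#' @param mean Sample mean.
#' @param sd Sample standard deviation (>= 0).
#' @return A `group_summary` list.
#' @export
group_summary <- function(n, mean, sd) {
  if (n < 2) stop("group_summary requires n >= 2")
  if (sd < 0) stop("sd must be >= 0")
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

#' Welch two-sample t-test from group summaries
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom,
#' computed from per-group n, mean and SD (as printed in a characteristics
#' table) rather than raw data.
#'
#' @param g1,g2 `group_summary` objects (or lists with `n`, `mean`, `sd`).
#' @return A `comparison_result` list: `kind = "welch_t"`, `statistic`, `df`,
#'   `p` (two-sided).
#' @examples
#' welch_t_from_summary(group_summary(2192, 9.17, 3.09),
#'                      group_summary(16928, 7.82, 2.92))
#' @export
welch_t_from_summary <- function(g1, g2) {
  v1 <- g1$sd^2 / g1$n
  v2 <- g2$sd^2 / g2$n
  if (v1 + v2 == 0) stop("undefined statistic: both groups have zero variance")
  t_stat <- (g1$mean - g2$mean) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  structure(list(kind = "welch_t", statistic = t_stat, df = df,
                 p = 2 * stats::pt(-abs(t_stat), df)),
            class = "comparison_result")
}

#' Pearson chi-square on a 2x2 table
#'
#' With the Yates continuity correction by default (the convention used for
#' the sex and admission-type comparisons).
#'
#' @param a,b,c,d Cell counts, row-wise: `rbind(c(a, b), c(c, d))`.
#' @param correction Apply the Yates correction (default TRUE).
#' @return A `comparison_result` list: `kind = "chi2_2x2"`, `statistic`,
#'   `df = 1`, `p`.
#' @export
chi2_2x2 <- function(a, b, c, d, correction = TRUE) {
  m <- rbind(c(a, b), c(c, d))
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero marginal total")
  ct <- suppressWarnings(stats::chisq.test(m, correct = correction))
  structure(list(kind = "chi2_2x2",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p = ct$p.value),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  lbl <- switch(x$kind, welch_t = "Welch t", student_t = "t",
                chi2_2x2 = "X^2", x$kind)
  cat(sprintf("%s = %.3f, df = %.1f, p = %.3g\n", lbl, x$statistic, x$df, x$p))
  invisible(x)
}

#' Compare unplanned-readmission and other patients on cohort characteristics
#'
#' Reproduces the layout of a cohort characteristics table: Welch t-tests for
#' age, length of stay, comorbidity score and LACE total; Yates-corrected
#' chi-square for sex and admission type. Records with unknown sex are dropped
#' from the sex row only.
#'
#' @param records Record data frame (single cohort).
#' @param scores Aligned data frame from [lace_score()].
#' @return Data frame with one row per characteristic: group summaries
#'   (n/mean/sd per group, or the 2x2 counts folded into `detail`), the test
#'   kind, statistic, df and p-value.
#' @export
compare_groups <- function(records, scores) {
  if (nrow(records) != nrow(scores)) stop("records and scores are misaligned")
  pos <- records$outcome == "unplanned_readmission"
  if (!any(pos)) stop("group empty: unplanned_readmission")
  if (!any(!pos)) stop("group empty: other")
  num_vars <- list(age = records$age, los = records$los_days,
                   comorbidity = scores$cci, lace = scores$lace_total)
  rows <- lapply(names(num_vars), function(v) {
    x <- num_vars[[v]]
    g1 <- group_summary(sum(pos), mean(x[pos]), stats::sd(x[pos]))
    g2 <- group_summary(sum(!pos), mean(x[!pos]), stats::sd(x[!pos]))
    r <- welch_t_from_summary(g1, g2)
    data.frame(variable = v, kind = r$kind,
               n_unplanned = g1$n, mean_unplanned = g1$mean,
               sd_unplanned = g1$sd,
               n_other = g2$n, mean_other = g2$mean, sd_other = g2$sd,
               statistic = r$statistic, df = r$df, p = r$p,
               stringsAsFactors = FALSE)
  })
  cat_vars <- list(
    sex = list(keep = records$sex != "unknown",
               level = records$sex == "male"),
    admission_type = list(keep = rep(TRUE, nrow(records)),
                          level = records$admission_type == "emergency"))
  cat_rows <- lapply(names(cat_vars), function(v) {
    keep <- cat_vars[[v]]$keep
    lv <- cat_vars[[v]]$level
    a <- sum(keep & pos & lv);  b <- sum(keep & pos & !lv)
    cc <- sum(keep & !pos & lv); d <- sum(keep & !pos & !lv)
    r <- if ((a + b) > 0 && (cc + d) > 0 && (a + cc) > 0 && (b + d) > 0)
      chi2_2x2(a, b, cc, d)
    else list(kind = "chi2_2x2", statistic = NA_real_, df = NA_real_,
              p = NA_real_)
    data.frame(variable = v, kind = r$kind,
               n_unplanned = a + b, mean_unplanned = a / (a + b),
               sd_unplanned = NA_real_,
               n_other = cc + d, mean_other = cc / (cc + d),
               sd_other = NA_real_,
               statistic = r$statistic, df = r$df, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, cat_rows))
  rownames(out) <- NULL
  out
}
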