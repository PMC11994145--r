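test_that("confusion_matrix counts flag/outcome combinations", {
  cm <- confusion_matrix(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(unclass(cm), list(tp = 1L, fp = 0L, fn = 0L, tn = 1L))
  expect_error(confusion_matrix(TRUE, c(TRUE, FALSE)), "equal length")
  expect_error(confusion_matrix(logical(0), logical(0)), "empty")
  cm <- confusion_matrix(c(1, 0, 1, 0), c(1, 1, 0, 0))
  expect_equal(with(cm, tp + fp + fn + tn), 4L)
})

test_that("screening metrics reproduce ratio definitions and handle degenerate cells", {
  # perfect classifier
  m <- classification_metrics(as_confusion_matrix(5, 0, 0, 7))
  expect_equal(m$sensitivity, 1); expect_equal(m$specificity, 1)
  expect_equal(m$ppv, 1); expect_equal(m$npv, 1); expect_equal(m$accuracy, 1)

  # nothing flagged: PPV undefined, reported NA with a warning, not zero
  cm0 <- confusion_matrix(rep(FALSE, 10), rep(c(TRUE, FALSE), 5))
  expect_warning(m0 <- classification_metrics(cm0), "ppv")
  expect_true(is.na(m0$ppv))
  expect_equal(m0$specificity, 1)
  expect_equal(m0$nir, 0.5)
})

test_that("Bayes and accuracy identities hold on random confusion matrices", {
  set.seed(77)
  for (i in 1:1000) {
    cm <- as_confusion_matrix(sample(1:200, 1), sample(1:200, 1),
                              sample(1:200, 1), sample(1:200, 1))
    m <- suppressWarnings(classification_metrics(cm))
    prev <- m$prevalence; sens <- m$sensitivity; spec <- m$specificity
    expect_equal(m$ppv,
                 prev * sens / (prev * sens + (1 - prev) * (1 - spec)))
    expect_equal(m$npv,
                 (1 - prev) * spec / ((1 - prev) * spec + prev * (1 - sens)))
    expect_equal(m$accuracy, prev * sens + (1 - prev) * spec)
    expect_equal(m$flagged_rate, prev * sens + (1 - prev) * (1 - spec))
    expect_true(m$accuracy_ci[1] <= m$accuracy &&
                  m$accuracy <= m$accuracy_ci[2])
    expect_equal(m$nir, max(prev, 1 - prev))
  }
})

test_that("Welch t from summaries equals t.test on raw data with those summaries", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(5:50, 1), sample(0:5, 1), runif(1, 0.5, 3))
    y <- rnorm(sample(5:50, 1), sample(0:5, 1), runif(1, 0.5, 3))
    mine <- welch_t_from_summary(
      group_summary(length(x), mean(x), sd(x)),
      group_summary(length(y), mean(y), sd(y)))
    ref <- t.test(x, y)  # Welch by default
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    # Welch df within [min(n1,n2)-1, n1+n2-2]
    expect_gte(mine$df, min(length(x), length(y)) - 1)
    expect_lte(mine$df, length(x) + length(y) - 2)
  }
  ident <- group_summary(10, 2.5, 1.1)
  expect_equal(welch_t_from_summary(ident, ident)$statistic, 0)
  z <- group_summary(5, 1, 0)
  expect_error(welch_t_from_summary(z, z), "zero variance")
})

test_that("chi-square on 2x2 tables: independence, Yates vs uncorrected, errors", {
  expect_equal(chi2_2x2(10, 10, 10, 10)$statistic, 0)
  expect_error(chi2_2x2(0, 0, 5, 5), "zero marginal")
  # Yates-corrected statistic never exceeds the uncorrected one
  set.seed(21)
  for (i in 1:200) {
    cells <- sample(1:100, 4, replace = TRUE)
    yates <- chi2_2x2(cells[1], cells[2], cells[3], cells[4])$statistic
    plain <- chi2_2x2(cells[1], cells[2], cells[3], cells[4],
                      correction = FALSE)$statistic
    expect_lte(yates, plain + 1e-12)
  }
  # hand oracle: sum((O-E)^2/E) without correction
  o <- c(12, 28, 35, 25)
  n <- sum(o)
  e <- outer(c(40, 60), c(47, 53)) / n
  expect_equal(chi2_2x2(12, 28, 35, 25, correction = FALSE)$statistic,
               sum((matrix(o, 2, byrow = TRUE) - e)^2 / e))
})

test_that("compare_groups reproduces the characteristics-table layout", {
  set.seed(5)
  prof <- cohort_profile("general", n = 800, seed = 5)
  rec <- generate_cohort(prof)
  sc <- lace_score(rec, charlson_score(rec))
  tab <- compare_groups(rec, sc)
  expect_setequal(tab$variable,
                  c("age", "los", "comorbidity", "lace", "sex",
                    "admission_type"))
  expect_identical(tab$kind[tab$variable == "lace"], "welch_t")
  expect_identical(tab$kind[tab$variable == "sex"], "chi2_2x2")
  # summaries echoed in the output equal ones recomputed from raw columns
  pos <- rec$outcome == "unplanned_readmission"
  expect_equal(tab$mean_unplanned[tab$variable == "age"], mean(rec$age[pos]))
  expect_equal(tab$sd_other[tab$variable == "lace"],
               sd(sc$lace_total[!pos]))
  expect_equal(tab$n_unplanned[tab$variable == "los"], sum(pos))

  # two identical outcome groups: all statistics zero
  rec2 <- rbind(rec, rec)
  rec2$outcome <- rep(c("unplanned_readmission", "other"), each = nrow(rec))
  sc2 <- rbind(sc, sc)
  tab2 <- compare_groups(rec2, sc2)
  expect_true(all(abs(tab2$statistic[tab2$kind == "welch_t"]) < 1e-12))
  expect_true(all(tab2$statistic[tab2$kind == "chi2_2x2"] == 0))

  rec3 <- rec; rec3$outcome <- "other"
  expect_error(compare_groups(rec3, sc), "unplanned_readmission")
})
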