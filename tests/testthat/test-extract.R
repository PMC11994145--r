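d <- build_default_dictionary()

test_that("normalization lower-cases, strips punctuation but keeps / and - inside tokens", {
  expect_equal(normalize_text("Known DM, HPT."), c("known", "dm", "hpt"))
  expect_equal(normalize_text(""), character(0))
  expect_equal(normalize_text("   \t "), character(0))
  expect_equal(normalize_text("CA w/o mets"), c("ca", "w/o", "mets"))
  expect_equal(normalize_text("end-organ damage!"), c("end-organ", "damage"))
  expect_equal(normalize_text("a - b / c"), c("a", "b", "c"))
})

test_that("condition matching follows longest-match, dedup and severity dominance", {
  m <- match_conditions(normalize_text("history of CCF and COPD"), d)
  expect_equal(nrow(m), 2)
  expect_equal(sort(m$weight), c(1, 1))

  # longest phrase consumes its tokens: no extra +2 for the inner "CA"
  m <- match_conditions(normalize_text("metastatic solid CA"), d)
  expect_equal(m$condition, "metastatic_solid_tumor")
  expect_equal(m$weight, 6)

  # synonyms of one concept count once
  m <- match_conditions(normalize_text("DM for years, diabetes follow-up"), d)
  expect_equal(m$condition, "diabetes")
  expect_equal(sum(m$weight), 2)

  # severity dominance within the liver group
  m <- match_conditions(normalize_text("mild liver disease now severe liver disease"), d)
  expect_equal(m$condition, "moderate_severe_liver_disease")
  expect_equal(m$weight, 3)

  # malignancy group: metastatic phrase dominates a separate bare mention
  m <- match_conditions(normalize_text("carcinoma with metastatic solid CA"), d)
  expect_equal(m$condition, "metastatic_solid_tumor")
  expect_equal(sum(m$weight), 6)

  # abbreviations match whole tokens only
  expect_equal(nrow(match_conditions(normalize_text("cascade academic demanding"), d)), 0)
  expect_equal(nrow(match_conditions(normalize_text("no history recorded"), d)), 0)
})

test_that("age points score one point per started decade above 40", {
  # oracle: decade intervals (40, 50] -> 1, (50, 60] -> 2, (60, 70] -> 3, (70, 80] -> 4
  expect_equal(age_points(c(0, 35, 40)), c(0L, 0L, 0L))
  expect_equal(age_points(c(41, 45, 50)), c(1L, 1L, 1L))
  expect_equal(age_points(c(51, 60, 61, 75, 100)), c(2L, 2L, 3L, 4L, 6L))
  expect_equal(age_points(40.5), 1L)  # fractional ages compared numerically
  expect_error(age_points(-1), "non-negative")
  # non-decreasing in age, zero on [0, 40]
  grid <- seq(0, 100, by = 0.5)
  pts <- age_points(grid)
  expect_true(all(diff(pts) >= 0))
  expect_true(all(pts[grid <= 40] == 0))
})

test_that("charlson_score adds retained condition weights and age points", {
  rec <- data.frame(
    history_text = c("metastatic solid CA", "", "jaundice"),
    age = c(35, 20, 52))
  expect_equal(charlson_score(rec, d), c(6L, 0L, 5L))
})

test_that("appending a dictionary phrase never decreases the score", {
  base_texts <- c("", "known DM", "history of CCF and COPD",
                  "mild liver disease", "carcinoma noted")
  set.seed(402)
  phrases <- d$phrase
  for (txt in base_texts) {
    s0 <- charlson_score(data.frame(history_text = txt, age = 30), d)
    for (p in sample(phrases, 12)) {
      s1 <- charlson_score(
        data.frame(history_text = paste(txt, "and", p), age = 30), d)
      expect_gte(s1, s0)
    }
  }
})

test_that("concordance is the exact agreement fraction", {
  expect_equal(concordance(rep(1:4, 13), rep(1:4, 13)), 1.0)
  a <- rep(0L, 52); b <- a; b[1:7] <- 1L
  expect_equal(concordance(a, b), 45 / 52)  # 0.8654, arithmetic oracle
  expect_error(concordance(1:3, 1:4), "equal length")
  expect_error(concordance(integer(0), integer(0)), "empty")
})
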