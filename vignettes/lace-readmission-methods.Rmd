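---
title: "Methods: LACE readmission scoring from free-text comorbidity extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LACE readmission scoring from free-text comorbidity extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lacescore)
```

## The problem

Roughly one admission in ten in surgical services is followed by an unplanned
return within 30 days of discharge. The LACE index is a widely used bedside
score for that risk, summing four components: **L**ength of stay (0–7
points), **A**cuity of admission (0 for elective, 3 for emergency),
**C**omorbidity (0–5 points from the Charlson Comorbidity Index, CCI) and
**E**mergency-department visits in the prior six months (0 or 4 points). The
total ranges 0–19 and a score of 10 or more conventionally flags high risk.

The practical obstacle in many hospital registries is the C component:
comorbidities are recorded only as free-text history-of-complaints
narratives. `lacescore` closes that gap with a weighted keyword dictionary:
surface phrases ("CCF", "metastatic solid CA", "jaundice", …) map to
Charlson categories carrying weights 1, 2, 3 or 6, and one point is added
per started decade of age above 40. The extracted CCI feeds the LACE C
component, the resulting flag is evaluated against the observed
unplanned-readmission outcome, and logistic models quantify the odds of
readmission per LACE point.

## Dictionary extraction

Extraction is deliberately simple keyword weighting, not general clinical
NLP:

* **Normalization.** Text is lower-cased and punctuation is mapped to
  whitespace, keeping `/` and `-` inside tokens so "CA w/o mets" and
  "end-organ damage" survive as written. No stemming, no spelling
  correction.
* **Longest match first.** Multi-token phrases are matched before shorter
  ones and consume their tokens: "metastatic solid CA" never additionally
  fires the bare "CA" entry. Ties are broken toward the higher weight.
* **One concept, one score.** Surface variants of a clinical concept ("DM"
  and "diabetes"; "stroke", "CVA" and "TIA"; "CHF", "CCF" and "congestive
  cardiac failure") share one canonical condition and count once per
  patient, because Charlson categories are scored per category, not per
  mention. Without this, a history mentioning a condition twice would
  inflate the cohort mean far above plausible values.
* **Severity dominance.** Within the liver group (mild +1 versus
  moderate/severe +3) and the malignancy group (non-metastatic +2 versus
  metastatic +6) only the highest matched weight is retained — the Charlson
  convention for severity-graded categories.
* **Whole-token abbreviations.** "DM" or "CA" never match inside longer
  words, minimizing false positives from two-letter abbreviations.
* **No negation or family-history handling.** "no DM" scores DM. The method
  is pure keyword extraction; negation detection is exposed nowhere because
  the extraction it emulates had none. The synthetic generator's
  `obfuscation_rate` exists to emulate the resulting machine–reviewer
  discrepancies when demonstrating the concordance operation.

Age points use `ceiling((age - 40) / 10)` above 40: ages 41–50 score 1,
51–60 score 2, and so on, with fractional ages compared numerically.

## LACE assembly

The L (length-of-stay) and C (comorbidity) point bands are the standard
published LACE lookups — L: <1 day 0, 1/2/3 days score 1/2/3, 4–6 days 4,
7–13 days 5, ≥14 days 7; C: CCI 0–3 carry over, ≥4 caps at 5 — chosen
because they reproduce the documented component ranges (L max 7, total max
19 = 7+3+5+4). Both tables are arguments to `lace_score()` and can be
overridden. The E component is binary by default (any visit scores 4,
matching the "0 or 4" convention); the standard graded `min(visits, 4)`
variant is available as `ed_mode = "graded"`. The high-risk threshold is
inclusive at 10 and configurable for threshold sweeps.

## Evaluation and inference

* Screening metrics come from the 2×2 confusion matrix of flag × outcome
  (positive class = unplanned readmission; "other" pools planned
  readmissions and non-readmitted patients). Accuracy gets an exact
  Clopper–Pearson 95% interval; on cohort-sized n this is conservative and
  indistinguishable from the printed widths of typical reports. Metrics
  with empty denominators are reported as `NA` with a warning, never
  silently as 0, so degenerate synthetic runs stay honest.
* Group comparisons use the **Welch** (unequal-variance) t-test. Recomputing
  published group statistics from printed summary cells reproduces the
  printed t values under Welch but not under pooled-variance Student, which
  is why the package implements the summary-based Welch form directly.
* 2×2 comparisons use the Pearson chi-square with **Yates** continuity
  correction by default, again because that is the variant that reproduces
  published sex-difference statistics in this setting.
* Logistic models are maximum-likelihood fits via iteratively reweighted
  least squares (`stats::glm`, binomial family, relative-deviance tolerance
  1e-10, max 50 iterations). Wald standard errors give `exp(beta ± 1.96 SE)`
  odds-ratio intervals, the symmetric-in-log form used in clinical
  reporting. Sex is coded male = 1 (the risk level in the trauma model);
  records with unknown sex are dropped from models using sex, with the
  count reported, but retained everywhere else. Zero-variance predictors
  and quasi-separation produce errors naming the term rather than quietly
  returning enormous coefficients.

## The synthetic cohort generator

No patient-level data ship with the package; the generator produces seeded
cohorts whose structure matches the two study populations the package was
built around, with ground truth stored for every stage:

| parameter | trauma | general surgery |
|---|---|---|
| n | 12,590 | 19,120 |
| unplanned prevalence | 804/12,590 | 2,192/19,120 |
| age (observed mean ± SD, truncated 18–100) | 33.91 ± 12.26 | 49.33 ± 17.44 |
| male | 85% | 47% |
| emergency admission | 95% | 49% |
| LOS (negative binomial, mean/SD) | 1.76 / 2.18 | 3.04 / 2.08 |
| mean text comorbidity score | 0.2 | 1.56 |
| ED visit rate (Poisson) | 0.35 | 0.45 |
| true LACE log-odds slope | 0.11 | 0.15 |
| covariate slope | sex: +0.52 | age: −0.004 |

Design choices that matter:

* **Ages** are drawn from the parent normal whose truncation to [18, 100]
  has exactly the target observed mean and SD (solved numerically), so the
  generated cohort moments converge to the table above, not to shifted
  values.
* **Length of stay** is negative binomial because the reported SDs exceed
  the means (over-dispersion); ED visits are Poisson. The ED visit rates
  are not reported for the study cohorts, so the defaults were chosen once
  to put the cohort mean LACE near the reported totals (5.91 trauma, 7.75
  general) and are profile fields like everything else.
* **Comorbidity targets.** The reported cohort mean comorbidity scores (0.2
  trauma, 1.56 general) cannot include age decade points — the general
  cohort's age distribution alone implies mean age points above 1 — so the
  generator interprets them as the text-derived condition component
  (`cci_text_mean`) and calibrates condition planting to hit that mean
  exactly in expectation. `gold_cci` still includes age points, exactly as
  `charlson_score()` computes them. A consequence is that generated LACE
  totals and flagged rates run somewhat above the reported cohort values;
  this affects face validity only, not any recovery property.
* **Condition planting** is independent Bernoulli per dictionary category
  with a prevalence-weighted mix (diabetes and coronary disease common,
  AIDS and metastatic disease rare). The planting rate solves a quadratic
  correction for severity-dominance overlap, making the expected planted
  score exact rather than approximate.
* **Histories** wrap each planted condition's surface form in a short
  opener and shuffle it among neutral filler sentences drawn from a frozen
  distractor list. The test suite screens every filler, opener and
  obfuscation phrase — including across sentence joins — against the
  dictionary, which is what makes the planted-term recovery oracle
  (extracted score == `gold_cci` on 100% of template histories) a real
  guarantee rather than a hope.
* **Outcomes** are Bernoulli draws from
  `plogis(alpha + lace_slope * LACE + covariate term)` where LACE is
  computed by the package's own scoring chain from the planted gold CCI
  (identical to the extracted CCI by the recovery property), so the fitted
  logistic model is correctly specified and slope-recovery checks are
  meaningful. The intercept `alpha` is calibrated by bisection so the
  expected prevalence matches the target to within 1e-6.

What the generator does *not* emulate: realistic clinical language (typos,
negations, abbreviations outside the dictionary), correlation between
comorbidity and age or LOS beyond what the outcome model induces, and
separate planned-readmission dynamics (pooled into "other"). Passing tests
on synthetic cohorts therefore validate the *computational chain* —
extraction, scoring, evaluation, inference — not the clinical performance
of the LACE index on any real registry.

## Problem sizes and numerical choices

The package's validation suite uses cohorts of 19,120 (20 replicates) for
odds-ratio recovery — the full study-scale n, at which the Wald SE of the
LACE slope is ≈0.008 and the mean fitted OR over 20 seeds is expected
within ±0.005 of exp(0.15) ≈ 1.162 — n = 6,000 for cohort-moment checks,
and 100 replicates of n = 2,000 for null-slope type-I calibration (95%
Wald CI coverage of OR = 1, accepted within three binomial standard errors
of nominal). Bisection for the intercept runs to |achieved − target| <
1e-9 with automatic bracket widening; the truncated-normal parent solve
uses Nelder–Mead to relative tolerance 1e-12. All randomness flows through
R's seeded generator; a profile plus a seed reproduces a cohort
byte-for-byte.

## Known limitations

* The dictionary is the fixed published term list, not a general clinical
  vocabulary; conditions phrased outside it (and negated mentions) are
  invisible to extraction.
* Published component bands for L and C were adopted from the standard LACE
  definition because the source tooling's own appendix mapping is not
  reproduced; both are overridable if a registry uses different bands.
* The concordance operation compares exact score equality only; it does not
  model reviewer behaviour.
* Reported cohort totals in the motivating tables are internally
  inconsistent in places (group sizes that do not sum to printed totals, a
  no-information rate not derivable from any printed count set); the
  package anchors on the self-consistent subset — sensitivity, specificity,
  predictive values, accuracy and group summary cells — and takes per-file
  counts as given.
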