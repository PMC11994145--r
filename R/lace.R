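#' @title LACE index scoring
#' @description Component point mappings for Length of stay, Acuity of
#'   admission, Comorbidity and Emergency-department visits, the 0-19 total,
#'   and the high-risk flag at the configurable threshold (default >= 10).
#' @name lace_scoring
NULL

# default banded lookup tables; both are config-overridable in lace_score()
.default_los_bands <- data.frame(lower = c(0L, 1L, 2L, 3L, 4L, 7L, 14L),
                                 points = c(0L, 1L, 2L, 3L, 4L, 5L, 7L))
.default_cci_bands <- data.frame(lower = c(0L, 1L, 2L, 3L, 4L),
                                 points = c(0L, 1L, 2L, 3L, 5L))

.band_lookup <- function(x, bands) {
  bands <- bands[order(bands$lower), , drop = FALSE]
  idx <- findInterval(x, bands$lower)
  if (any(idx == 0L)) stop("value below the lowest band")
  as.integer(bands$points[idx])
}

#' Length-of-stay points (L)
#'
#' Banded 0-7 mapping of length of stay in days: <1 day scores 0, then 1, 2
#' and 3 days score their own value, 4-6 days score 4, 7-13 days score 5, and
#' 14 days or more caps at 7.
#'
#' @param los_days Non-negative numeric vector of days.
#' @param bands Optional override lookup (`data.frame(lower, points)`).
#' @return Integer points, 0-7 under the default bands.
#' @export
los_points <- function(los_days, bands = .default_los_bands) {
  if (any(is.na(los_days)) || any(los_days < 0))
    stop("los_days must be non-negative")
  .band_lookup(los_days, bands)
}

#' Acuity-of-admission points (A)
#'
#' Emergency admission scores 3, elective scores 0.
#'
#' @param admission_type Character vector, each element "elective" or
#'   "emergency".
#' @return Integer points (0 or 3).
#' @export
acuity_points <- function(admission_type) {
  bad <- !(admission_type %in% c("elective", "emergency"))
  if (any(bad)) stop("unknown admission_type: ",
                     paste(unique(admission_type[bad]), collapse = ", "))
  ifelse(admission_type == "emergency", 3L, 0L)
}

#' Comorbidity points (C)
#'
#' Maps the Charlson comorbidity score onto the 0-5 LACE comorbidity band:
#' scores 0-3 carry over directly, scores of 4 or more cap at 5 (keeping the
#' maximum total at 19).
#'
#' @param cci Non-negative integer vector of Charlson scores.
#' @param bands Optional override lookup (`data.frame(lower, points)`).
#' @return Integer points, 0-5 under the default bands.
#' @export
comorbidity_points <- function(cci, bands = .default_cci_bands) {
  if (any(is.na(cci)) || any(cci < 0)) stop("cci must be non-negative")
  .band_lookup(cci, bands)
}

#' Emergency-department visit points (E)
#'
#' In the default `"binary"` mode any ED visit in the prior six months scores
#' 4 and none scores 0. The `"graded"` mode is the standard alternative
#' `min(visits, 4)`.
#'
#' @param ed_visits_6mo Non-negative integer vector of visit counts.
#' @param mode `"binary"` (default) or `"graded"`.
#' @return Integer points, 0-4.
#' @export
ed_points <- function(ed_visits_6mo, mode = c("binary", "graded")) {
  mode <- match.arg(mode)
  if (any(is.na(ed_visits_6mo)) || any(ed_visits_6mo < 0))
    stop("ed_visits_6mo must be non-negative")
  if (mode == "binary") ifelse(ed_visits_6mo >= 1, 4L, 0L)
  else as.integer(pmin(ed_visits_6mo, 4L))
}

#' LACE components, total and high-risk flag for a cohort
#'
#' Computes the four LACE sub-scores from the admission record and its
#' comorbidity score, the 0-19 total, and the high-risk flag at the given
#' threshold (default: total >= 10 flags high risk).
#'
#' @param records Data frame with columns `los_days`, `admission_type`,
#'   `ed_visits_6mo` (a full patient cohort works directly).
#' @param cci Integer vector of Charlson scores aligned with `records`,
#'   e.g. from [charlson_score()].
#' @param ed_mode Passed to [ed_points()].
#' @param threshold High-risk cut-off on the total, in \[0, 19\].
#' @param los_bands,cci_bands Optional band overrides for [los_points()] and
#'   [comorbidity_points()].
#' @return Data frame with columns `cci`, `l_points`, `a_points`, `c_points`,
#'   `e_points`, `lace_total`, `high_risk`, one row per record.
#' @examples
#' rec <- data.frame(los_days = 30, admission_type = "emergency",
#'                   ed_visits_6mo = 1)
#' lace_score(rec, cci = 6)  # total 19, high_risk TRUE
#' @export
lace_score <- function(records, cci, ed_mode = c("binary", "graded"),
                       threshold = 10L,
                       los_bands = .default_los_bands,
                       cci_bands = .default_cci_bands) {
  ed_mode <- match.arg(ed_mode)
  stopifnot(is.data.frame(records),
            all(c("los_days", "admission_type", "ed_visits_6mo") %in%
                  names(records)))
  if (length(cci) != nrow(records))
    stop("cci must align with records (length mismatch)")
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 19)
    stop("threshold must be a single value in [0, 19]")
  l <- los_points(records$los_days, los_bands)
  a <- acuity_points(records$admission_type)
  c_ <- comorbidity_points(cci, cci_bands)
  e <- ed_points(records$ed_visits_6mo, ed_mode)
  total <- l + a + c_ + e
  data.frame(cci = as.integer(cci), l_points = l, a_points = a,
             c_points = c_, e_points = e, lace_total = total,
             high_risk = total >= threshold)
}
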