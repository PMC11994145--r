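#' @title Admission-record input/output
#' @description Read, validate, filter and write patient admission records in
#'   the pipeline's tabular schema (CSV per RFC 4180 or JSON-lines, UTF-8).
#' @name records_io
NULL

.required_cols <- c("patient_id", "cohort", "age", "sex", "admission_type",
                    "los_days", "ed_visits_6mo", "history_text", "outcome")
.score_cols <- c("cci", "l_points", "a_points", "c_points", "e_points",
                 "lace_total", "high_risk")

.normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("m", "male")] <- "male"
  out[x %in% c("f", "female")] <- "female"
  out
}

.parse_enum <- function(x, levels, field, extra_aliases = list()) {
  raw <- tolower(trimws(as.character(x)))
  val <- raw
  for (alias in names(extra_aliases)) val[raw == alias] <- extra_aliases[[alias]]
  bad <- !(val %in% levels)
  if (any(bad))
    stop(sprintf("unparseable %s value(s) at row(s) %s: %s", field,
                 paste(utils::head(which(bad), 5L), collapse = ", "),
                 paste(utils::head(unique(raw[bad]), 5L), collapse = ", ")))
  val
}

.parse_num <- function(x, field, integer = FALSE) {
  raw <- trimws(as.character(x))
  val <- suppressWarnings(as.numeric(raw))
  bad <- is.na(val)
  if (any(bad))
    stop(sprintf("non-numeric %s at row(s) %s", field,
                 paste(utils::head(which(bad), 5L), collapse = ", ")))
  if (integer) as.integer(val) else val
}

# coerce a raw character data frame into the typed record schema
.coerce_records <- function(d) {
  names(d) <- tolower(names(d))
  missing <- setdiff(.required_cols, names(d))
  if (length(missing) > 0L)
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  out <- data.frame(
    patient_id = as.character(d$patient_id),
    cohort = .parse_enum(d$cohort, c("trauma", "general"), "cohort",
                         list("general surgery" = "general")),
    age = .parse_num(d$age, "age"),
    sex = .normalize_sex(d$sex),
    admission_type = .parse_enum(d$admission_type,
                                 c("elective", "emergency"), "admission_type"),
    los_days = .parse_num(d$los_days, "los_days", integer = TRUE),
    ed_visits_6mo = .parse_num(d$ed_visits_6mo, "ed_visits_6mo",
                               integer = TRUE),
    history_text = as.character(d$history_text),
    outcome = .parse_enum(d$outcome, c("unplanned_readmission", "other"),
                          "outcome",
                          list("unplanned" = "unplanned_readmission",
                               "unplanned readmission" =
                                 "unplanned_readmission")),
    stringsAsFactors = FALSE)
  if ("gold_cci" %in% names(d)) {
    g <- trimws(as.character(d$gold_cci))
    out$gold_cci <- ifelse(nzchar(g) & !is.na(g),
                           suppressWarnings(as.integer(g)), NA_integer_)
  }
  for (col in .score_cols) {
    if (!(col %in% names(d))) next
    out[[col]] <- if (col == "high_risk") as.logical(d[[col]])
                  else .parse_num(d[[col]], col, integer = TRUE)
  }
  validate_records(out)
  out
}

#' Validate a record data frame against the schema invariants
#'
#' Checks non-negative length of stay, visit counts and gold scores, and the
#' closed outcome/admission/sex vocabularies. Returns the records invisibly so
#' it can sit in a pipeline.
#'
#' @param records Data frame in the admission-record schema.
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(.required_cols, names(records))
  if (length(missing) > 0L)
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (any(records$los_days < 0, na.rm = TRUE)) stop("los_days must be >= 0")
  if (any(records$ed_visits_6mo < 0, na.rm = TRUE))
    stop("ed_visits_6mo must be >= 0")
  if (any(records$age < 0, na.rm = TRUE)) stop("age must be >= 0")
  if (!all(records$outcome %in% c("unplanned_readmission", "other")))
    stop("outcome must be unplanned_readmission or other")
  if (!is.null(records$gold_cci) && any(records$gold_cci < 0, na.rm = TRUE))
    stop("gold_cci must be >= 0 when present")
  invisible(records)
}

#' Read an admission cohort from CSV or JSON-lines
#'
#' Column/key names are matched case-insensitively against the schema
#' `patient_id, cohort, age, sex, admission_type, los_days, ed_visits_6mo,
#' history_text, outcome[, gold_cci]`. Sex values `M`/`F`/`male`/`female`
#' (any case) are normalized and anything else becomes `"unknown"`;
#' unparseable `admission_type` or `outcome` values are an error. Row order is
#' preserved. Score columns written by [write_scored()] are read back typed.
#'
#' @param path Input file.
#' @param format `"csv"` or `"jsonl"` (one JSON object per line).
#' @return Data frame of typed records in file order.
#' @export
read_cohort <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- if (format == "csv") {
    utils::read.csv(path, colClasses = "character", check.names = TRUE,
                    fileEncoding = "UTF-8")
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty jsonl file: ", path)
    rows <- lapply(lines, function(l) {
      x <- jsonlite::fromJSON(l)
      x[vapply(x, is.null, logical(1))] <- NA
      as.data.frame(lapply(x, as.character), stringsAsFactors = FALSE)
    })
    nm <- unique(unlist(lapply(rows, names)))
    do.call(rbind, lapply(rows, function(r) {
      r[setdiff(nm, names(r))] <- NA_character_
      r[nm]
    }))
  }
  .coerce_records(d)
}

#' Age-based eligibility filter
#'
#' Keeps records with age between 18 and 100 inclusive (patients younger than
#' 18 or older than 100 are excluded from analysis); fractional ages are
#' compared numerically. Order is preserved and the operation is idempotent.
#'
#' @param records Record data frame.
#' @return List with `kept` (the eligible records) and `n_excluded`.
#' @export
apply_eligibility_filter <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) return(list(kept = records, n_excluded = 0L))
  keep <- records$age >= 18 & records$age <= 100
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, n_excluded = as.integer(sum(!keep)))
}

#' Write a scored cohort
#'
#' Appends the LACE score columns of [lace_score()] to the original records
#' and writes the result; [read_cohort()] on the output reproduces every field.
#'
#' @param records Record data frame.
#' @param scores Aligned data frame from [lace_score()] (same row count).
#' @param path Output file.
#' @param format `"csv"` or `"jsonl"`.
#' @return The output path, invisibly.
#' @export
write_scored <- function(records, scores, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (nrow(records) != nrow(scores))
    stop("records and scores are misaligned (", nrow(records), " vs ",
         nrow(scores), " rows)")
  out <- cbind(records, scores)
  names(out)[names(out) == "high_risk"] <- "high_risk"
  if (format == "csv") {
    utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(out)))
      writeLines(jsonlite::toJSON(as.list(out[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA,
                                  na = "null"), con)
  }
  invisible(path)
}
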