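#' @title Free-text comorbidity extraction
#' @description Tokenization, longest-phrase-first dictionary matching and
#'   Charlson scoring of free-text patient histories.
#' @name comorbidity_extraction
NULL

# vectorized normalization to a single space-separated token string
.norm_vec <- function(x) {
  x <- tolower(as.character(x))
  x[is.na(x)] <- ""
  x <- gsub("[‐‑‒–—−]", "-", x)
  x <- gsub("[^a-z0-9/-]+", " ", x)
  # "/" and "-" survive only inside tokens
  x <- gsub("(?<=^|\\s)[-/]+", "", x, perl = TRUE)
  x <- gsub("[-/]+(?=\\s|$)", "", x, perl = TRUE)
  gsub("\\s+", " ", trimws(x))
}

# phrases are normalized to [a-z0-9 /-]; escape anything else defensively
.rx_escape <- function(x) gsub("([^a-z0-9 /])", "\\\\\\1", x, perl = TRUE)

#' Normalize free text to a token sequence
#'
#' Lower-cases, maps punctuation to whitespace (keeping `/` and `-` inside
#' tokens, so phrases such as "CA w/o mets" and "end-organ damage" survive as
#' written) and splits on whitespace. Deterministic; no stemming or spelling
#' correction.
#'
#' @param raw A single character string (NA treated as empty).
#' @return Character vector of tokens; `character(0)` for empty input.
#' @examples
#' normalize_text("Known DM, HPT.")  # "known" "dm" "hpt"
#' @export
normalize_text <- function(raw) {
  stopifnot(length(raw) == 1L)
  s <- .norm_vec(raw)
  if (!nzchar(s)) return(character(0))
  strsplit(s, " ", fixed = TRUE)[[1]]
}

# ordered matcher over a vector of normalized strings; returns a logical
# matrix records x canonical conditions. Longest phrase first (ties broken by
# higher weight); matched spans are consumed so shorter phrases cannot re-fire
# inside them.
.match_matrix <- function(norm, dictionary) {
  canon <- dictionary_conditions(dictionary)
  ord <- order(-lengths(strsplit(dictionary$phrase_norm, " ", fixed = TRUE)),
               -dictionary$weight)
  mat <- matrix(FALSE, nrow = length(norm), ncol = nrow(canon),
                dimnames = list(NULL, canon$canonical))
  live <- nzchar(norm)
  for (i in ord) {
    pat <- paste0("(?<=^|\\s)", .rx_escape(dictionary$phrase_norm[i]),
                  "(?=\\s|$)")
    hit <- live & grepl(pat, norm, perl = TRUE)
    if (any(hit)) {
      mat[hit, dictionary$canonical[i]] <- TRUE
      norm[hit] <- gsub(pat, "", norm[hit], perl = TRUE)
    }
  }
  mat
}

# within each severity group keep only the highest-weight matched condition
.apply_dominance <- function(mat, canon) {
  for (g in unique(canon$group[!is.na(canon$group)])) {
    members <- which(canon$group %in% g)
    members <- members[order(-canon$weight[members])]
    if (length(members) < 2L) next
    seen <- rep(FALSE, nrow(mat))
    for (m in members) {
      mat[seen, m] <- FALSE
      seen <- seen | mat[, m]
    }
  }
  mat
}

#' Match dictionary conditions in a token sequence
#'
#' Greedy longest-phrase-first matching: tokens consumed by a longer phrase
#' are unavailable to shorter ones (so "metastatic solid CA" never also fires
#' a bare "CA"), each canonical condition counts at most once however many
#' times it is mentioned, and within a severity group (liver, malignancy) only
#' the highest-weight matched condition is retained.
#'
#' @param tokens Character vector of tokens from [normalize_text()] (a single
#'   raw string is normalized first).
#' @param dictionary A `lace_dictionary`.
#' @return Data frame with columns `condition`, `weight`, `group` — the
#'   retained matches; zero rows when nothing matches.
#' @examples
#' d <- build_default_dictionary()
#' match_conditions(normalize_text("history of CCF and COPD"), d)
#' @export
match_conditions <- function(tokens, dictionary) {
  if (length(tokens) == 1L && grepl("\\s", tokens)) tokens <- normalize_text(tokens)
  s <- paste(tokens, collapse = " ")
  canon <- dictionary_conditions(dictionary)
  mat <- .apply_dominance(.match_matrix(s, dictionary), canon)
  keep <- which(mat[1L, ])
  data.frame(condition = canon$canonical[keep],
             weight = canon$weight[keep],
             group = canon$group[keep],
             stringsAsFactors = FALSE)
}

#' Charlson age points
#'
#' One point per started decade of age above 40: 0 points up to age 40, then
#' 41-50 scores 1, 51-60 scores 2, and so on (`ceiling((age - 40)/10)`).
#' Fractional ages are compared numerically.
#'
#' @param age Numeric vector of ages in years, all `>= 0`.
#' @return Integer vector of age points.
#' @export
age_points <- function(age) {
  if (any(is.na(age)) || any(age < 0)) stop("age must be non-negative")
  as.integer(ifelse(age <= 40, 0L, ceiling((age - 40) / 10)))
}

# condition-weight sum with severity dominance for a set of canonicals
score_condition_set <- function(conditions, dictionary) {
  canon <- dictionary_conditions(dictionary)
  i <- match(unique(conditions), canon$canonical)
  if (anyNA(i)) stop("unknown condition(s): ",
                     paste(unique(conditions)[is.na(i)], collapse = ", "))
  if (length(i) == 0L) return(0L)
  keep <- canon[i, , drop = FALSE]
  grouped <- !is.na(keep$group)
  total <- sum(keep$weight[!grouped])
  if (any(grouped))
    total <- total + sum(tapply(keep$weight[grouped], keep$group[grouped], max))
  as.integer(total)
}

#' Charlson comorbidity score from free text and age
#'
#' The comorbidity score is the sum of the weights of the dictionary
#' conditions retained in the history text (after synonym deduplication and
#' severity dominance) plus the age decade points of [age_points()].
#'
#' @param records Data frame with columns `history_text` and `age` (a full
#'   patient cohort works directly).
#' @param dictionary A `lace_dictionary`; defaults to the built-in one.
#' @return Integer vector of scores, one per row of `records`.
#' @examples
#' d <- build_default_dictionary()
#' charlson_score(data.frame(history_text = "metastatic solid CA", age = 35), d)
#' @export
charlson_score <- function(records, dictionary = build_default_dictionary()) {
  stopifnot(is.data.frame(records),
            all(c("history_text", "age") %in% names(records)))
  canon <- dictionary_conditions(dictionary)
  mat <- .apply_dominance(.match_matrix(.norm_vec(records$history_text),
                                        dictionary), canon)
  as.integer(mat %*% canon$weight) + age_points(records$age)
}

#' Exact concordance between two score sequences
#'
#' Fraction of positions where two integer score sequences agree exactly; used
#' to compare machine-extracted comorbidity scores with a reference scorer
#' (e.g. expert review, or the planted gold scores of a synthetic cohort).
#'
#' @param scores_a,scores_b Equal-length numeric vectors, length >= 1.
#' @return Proportion in \[0, 1\].
#' @export
concordance <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop("score sequences must have equal length")
  if (length(scores_a) == 0L) stop("empty score sequences")
  mean(scores_a == scores_b)
}
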