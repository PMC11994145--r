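#' Weighted comorbidity keyword dictionary
#'
#' The extraction dictionary maps surface phrases found in free-text patient
#' histories onto Charlson comorbidity categories. Each entry carries an
#' integer Charlson weight (1, 2, 3 or 6); surface variants of the same
#' clinical concept (e.g. "DM" and "diabetes", or "stroke" and "CVA") share a
#' canonical condition so that one concept scores at most once per patient.
#' Severity-graded concepts (liver disease, malignancy) additionally share a
#' `severity_group`: when several members of a group match the same history,
#' only the highest-weight member is retained.
#'
#' @name lace_dictionary
#' @seealso [build_default_dictionary()], [match_conditions()], [charlson_score()]
NULL

# canonical, group (NA = no dominance group), weight, surface forms as printed
.default_dictionary_rows <- function() {
  list(
    list("myocardial_infarction", NA, 1L, c("myocardial infarction")),
    list("coronary_artery_disease", NA, 1L,
         c("coronary artery disease", "CAD", "angina", "coronary angioplasty",
           "bypass surgery", "stenting")),
    list("heart_failure", NA, 1L,
         c("CHF", "CFF", "CCF", "congestive cardiac failure",
           "congestive heart failure")),
    list("peripheral_vascular_disease", NA, 1L,
         c("PVD", "gangrene", "acute ischemia", "aneurysm")),
    list("cerebrovascular_disease", NA, 1L,
         c("CVA", "CVD", "stroke", "TIA", "transient ischemic attacks")),
    list("dementia", NA, 1L, c("dementia")),
    list("chronic_pulmonary_disease", NA, 1L,
         c("COPD", "OAD", "obstructive airways disease", "emphysema")),
    list("peptic_ulcer_disease", NA, 1L, c("PUD")),
    list("mild_liver_disease", "liver", 1L,
         c("mild liver disease", "cirrhosis", "hepatitis")),
    list("moderate_severe_liver_disease", "liver", 3L,
         c("moderate liver disease", "severe liver disease", "jaundice")),
    list("renal_disease", NA, 2L,
         c("moderate-severe CKD", "ESRD", "end stage renal disease",
           "renal disease")),
    list("diabetes", NA, 2L,
         c("DM", "diabetes", "DM with end-organ damage",
           "diabetes with retinopathy", "diabetes with nephropathy",
           "diabetes with neuropathy", "diabetic foot",
           "diabetes + amputation")),
    list("leukemia", NA, 2L,
         c("CLL", "chronic lymphocytic leukemia", "leukemia")),
    list("malignancy", "malignancy", 2L,
         c("CA w/o mets", "MASS nonmalignant", "carcinoma", "CA", "mass",
           "carcinoma + malignant")),
    list("metastatic_solid_tumor", "malignancy", 6L, c("metastatic solid CA")),
    list("aids", NA, 6L, c("AIDS"))
  )
}

#' Build the default comorbidity dictionary
#'
#' Constructs the built-in weighted keyword dictionary: 16 canonical Charlson
#' categories covering the +1 row (myocardial infarction, heart failure,
#' peripheral vascular and cerebrovascular disease, dementia, chronic
#' pulmonary disease, peptic ulcer, mild liver disease, coronary artery
#' disease with its procedural synonyms), the +2 row (renal disease, diabetes,
#' leukemia, non-metastatic malignancy), the +3 liver row (moderate/severe
#' liver disease, jaundice) and the +6 row (metastatic solid cancer, AIDS).
#' Age decade points above 40 are handled separately by [age_points()], not by
#' a dictionary entry.
#'
#' @return A `lace_dictionary`: a data frame with one row per surface form and
#'   columns `canonical`, `group`, `weight`, `phrase` (as printed) and
#'   `phrase_norm` (the normalized token form actually matched), plus a
#'   `version` attribute.
#' @examples
#' dict <- build_default_dictionary()
#' lookup_weight(dict, "AIDS")     # 6
#' lookup_weight(dict, "jaundice") # 3
#' @export
build_default_dictionary <- function() {
  rows <- .default_dictionary_rows()
  d <- do.call(rbind, lapply(rows, function(r) {
    data.frame(canonical = r[[1]], group = r[[2]], weight = r[[3]],
               phrase = r[[4]], stringsAsFactors = FALSE)
  }))
  d$phrase_norm <- vapply(d$phrase, function(p)
    paste(normalize_text(p), collapse = " "), character(1), USE.NAMES = FALSE)
  new_dictionary(d, version = "builtin-1")
}

#' Construct a dictionary from a surface-form table
#'
#' @param entries Data frame with columns `canonical`, `group` (NA allowed),
#'   `weight` (integer in 1, 2, 3, 6) and `phrase`.
#' @param version Version tag stored on the object.
#' @return A validated `lace_dictionary`.
#' @export
new_dictionary <- function(entries, version = "custom") {
  stopifnot(is.data.frame(entries),
            all(c("canonical", "weight", "phrase") %in% names(entries)))
  if (is.null(entries$group)) entries$group <- NA_character_
  if (is.null(entries$phrase_norm)) {
    entries$phrase_norm <- vapply(entries$phrase, function(p)
      paste(normalize_text(p), collapse = " "), character(1), USE.NAMES = FALSE)
  }
  if (!all(entries$weight %in% c(1L, 2L, 3L, 6L)))
    stop("dictionary weights must be in {1, 2, 3, 6}")
  if (any(!nzchar(entries$phrase_norm)))
    stop("every surface form must normalize to a non-empty token sequence")
  dup <- duplicated(entries$phrase_norm)
  if (any(dup))
    stop("duplicate normalized surface form(s): ",
         paste(unique(entries$phrase_norm[dup]), collapse = ", "))
  # one weight per canonical condition
  w_by_canon <- tapply(entries$weight, entries$canonical,
                       function(w) length(unique(w)))
  if (any(w_by_canon != 1L))
    stop("a canonical condition must have a single weight")
  rownames(entries) <- NULL
  structure(entries, class = c("lace_dictionary", "data.frame"),
            version = version)
}

#' Weight of the condition matched by a single phrase
#'
#' @param dictionary A `lace_dictionary`.
#' @param phrase A surface form (matched case-insensitively after
#'   normalization).
#' @return Integer Charlson weight, or an error if the phrase is not in the
#'   dictionary.
#' @export
lookup_weight <- function(dictionary, phrase) {
  key <- paste(normalize_text(phrase), collapse = " ")
  i <- match(key, dictionary$phrase_norm)
  if (is.na(i)) stop("phrase not in dictionary: ", phrase)
  dictionary$weight[i]
}

#' Canonical condition table of a dictionary
#'
#' One row per canonical condition with its weight and severity group.
#' @param dictionary A `lace_dictionary`.
#' @return Data frame with columns `canonical`, `group`, `weight`.
#' @export
dictionary_conditions <- function(dictionary) {
  u <- !duplicated(dictionary$canonical)
  data.frame(canonical = dictionary$canonical[u],
             group = dictionary$group[u],
             weight = dictionary$weight[u],
             stringsAsFactors = FALSE)
}

#' Serialize a dictionary to versioned JSON
#'
#' @param dictionary A `lace_dictionary`.
#' @param path Output file path.
#' @export
write_dictionary <- function(dictionary, path) {
  canon <- dictionary_conditions(dictionary)
  entries <- lapply(seq_len(nrow(canon)), function(i) {
    cc <- canon$canonical[i]
    e <- list(canonical_condition = cc,
              surface_forms = dictionary$phrase[dictionary$canonical == cc],
              weight = canon$weight[i])
    if (!is.na(canon$group[i])) e$severity_group <- canon$group[i]
    e
  })
  jsonlite::write_json(list(version = attr(dictionary, "version"),
                            entries = entries),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a dictionary from its JSON serialization
#'
#' @param path JSON file written by [write_dictionary()] (or hand-authored in
#'   the same shape).
#' @return A `lace_dictionary`.
#' @export
read_dictionary <- function(path) {
  x <- jsonlite::read_json(path)
  rows <- do.call(rbind, lapply(x$entries, function(e) {
    g <- unlist(e$severity_group)
    data.frame(canonical = e$canonical_condition,
               group = if (length(g) == 0L) NA_character_ else g,
               weight = as.integer(e$weight),
               phrase = unlist(e$surface_forms),
               stringsAsFactors = FALSE)
  }))
  new_dictionary(rows, version = if (is.null(x$version)) "custom" else x$version)
}

#' @export
print.lace_dictionary <- function(x, ...) {
  canon <- dictionary_conditions(x)
  cat(sprintf("<lace_dictionary %s: %d conditions, %d surface forms>\n",
              attr(x, "version"), nrow(canon), nrow(x)))
  for (w in sort(unique(canon$weight)))
    cat(sprintf("  +%d: %s\n", w,
                paste(canon$canonical[canon$weight == w], collapse = ", ")))
  invisible(x)
}
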