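#' @title Pipeline orchestration
#' @description Wires the stages simulate -> extract -> score -> evaluate ->
#'   model behind a single configurable entry point, writing scored records,
#'   a metrics report and model coefficient tables to disk.
#' @name pipeline
NULL

.default_config <- list(
  input = NULL, profile = "general", n = NULL, seed = 1L,
  format = "csv", out_dir = ".", ed_mode = "binary", threshold = 10L,
  dictionary = NULL, obfuscation_rate = NULL, log_level = "info")

#' Validate and complete a pipeline configuration
#'
#' @param config Named list (or path to a JSON/YAML-free JSON config file);
#'   unknown keys are rejected, missing keys take defaults. Either `input`
#'   (an existing records file) or a simulation `profile` must be usable.
#' @return The completed config list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(config), names(.default_config))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.default_config, config)
  if (!is.null(cfg$threshold) &&
      (cfg$threshold < 0 || cfg$threshold > 19))
    stop("threshold must be in [0, 19]")
  if (!is.null(cfg$input) && !file.exists(cfg$input))
    stop("input file not found: ", cfg$input)
  if (!cfg$ed_mode %in% c("binary", "graded"))
    stop("ed_mode must be binary or graded")
  if (!is.null(cfg$dictionary) && !file.exists(cfg$dictionary))
    stop("dictionary file not found: ", cfg$dictionary)
  cfg
}

.log_stage <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf(...))
}

# stable fingerprint of the effective config, embedded in every artifact
.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the readmission-risk pipeline
#'
#' Executes, in order: record acquisition (reading `config$input`, or
#' simulating a cohort with the named profile when no input is given),
#' eligibility filtering (ages 18-100), comorbidity extraction from free
#' text, LACE scoring, screening evaluation against the unplanned-readmission
#' outcome, group comparisons, and the per-cohort logistic models. Per-stage
#' record counts are logged; artifacts (`scored.csv`, `metrics.json`,
#' `models.json`) are written under `config$out_dir` and embed the config
#' fingerprint and seed for provenance.
#'
#' @param config See [pipeline_config()].
#' @return Invisibly, a list with `records`, `scores`, `metrics`,
#'   `comparisons`, `models`, `artifacts` (paths) and `config`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  dict <- if (is.null(cfg$dictionary)) build_default_dictionary()
          else read_dictionary(cfg$dictionary)
  if (!is.null(cfg$input)) {
    records <- read_cohort(cfg$input, cfg$format)
    .log_stage(cfg, "read: %d records from %s", nrow(records), cfg$input)
  } else {
    prof_args <- list(profile = cfg$profile, seed = as.integer(cfg$seed))
    if (!is.null(cfg$n)) prof_args$n <- as.integer(cfg$n)
    if (!is.null(cfg$obfuscation_rate))
      prof_args$obfuscation_rate <- cfg$obfuscation_rate
    profile <- do.call(cohort_profile, prof_args)
    records <- generate_cohort(profile, seed = cfg$seed, dictionary = dict,
                               ed_mode = cfg$ed_mode)
    .log_stage(cfg, "simulate: %d records (profile %s, seed %d)",
               nrow(records), cfg$profile, as.integer(cfg$seed))
  }
  flt <- apply_eligibility_filter(records)
  records <- flt$kept
  .log_stage(cfg, "eligibility filter: %d kept, %d excluded",
             nrow(records), flt$n_excluded)

  cci <- charlson_score(records, dict)
  .log_stage(cfg, "extract: mean comorbidity score %.3f", mean(cci))
  scores <- lace_score(records, cci, ed_mode = cfg$ed_mode,
                       threshold = cfg$threshold)
  .log_stage(cfg, "score: mean LACE %.2f, %d flagged high risk",
             mean(scores$lace_total), sum(scores$high_risk))

  cm <- confusion_matrix(scores$high_risk,
                         records$outcome == "unplanned_readmission")
  metrics <- classification_metrics(cm)
  comparisons <- compare_groups(records, scores)
  models <- fit_cohort_models(records, scores)
  .log_stage(cfg, "evaluate: sensitivity %.4f, specificity %.4f",
             metrics$sensitivity, metrics$specificity)

  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  prov <- list(config_hash = .config_hash(cfg), seed = as.integer(cfg$seed),
               n_excluded = flt$n_excluded)
  scored_path <- file.path(cfg$out_dir, "scored.csv")
  write_scored(records, scores, scored_path, "csv")
  metrics_path <- file.path(cfg$out_dir, "metrics.json")
  jsonlite::write_json(
    c(prov, list(confusion = unclass(cm),
                 metrics = unclass(metrics),
                 comparisons = comparisons)),
    metrics_path, auto_unbox = TRUE, digits = NA, na = "null")
  models_path <- file.path(cfg$out_dir, "models.json")
  jsonlite::write_json(
    c(prov, list(models = lapply(models, function(m)
      c(list(n = m$n, n_dropped = attr(m, "n_dropped"),
             log_likelihood = m$log_likelihood),
        list(coefficients = coef_table(m)))))),
    models_path, auto_unbox = TRUE, digits = NA, na = "null")
  .log_stage(cfg, "artifacts: %s", paste(c(scored_path, metrics_path,
                                           models_path), collapse = ", "))
  invisible(list(records = records, scores = scores, metrics = metrics,
                 comparisons = comparisons, models = models,
                 artifacts = c(scored = scored_path, metrics = metrics_path,
                               models = models_path),
                 config = cfg))
}
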