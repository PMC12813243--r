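#' Pipeline configuration
#'
#' Bundles every analysis setting: input/output paths, the date window,
#' SMQ scope policy, comparator construction, the Wald level, screen and
#' cascade thresholds, and the seed used by any simulation step.
#'
#' @param input_dir Directory with the six FAERS-style ASCII tables.
#' @param output_dir Run directory (created on [run_pipeline()]).
#' @param smq_definitions,smq_terms Paths of the SMQ dictionary files;
#'   `NULL` uses the packaged toy dictionary.
#' @param lexicon Path of the drug lexicon; `NULL` uses the packaged one.
#' @param indication_pts Indication substrings (see [build_cohort()]).
#' @param date_window Integer `c(from, to)` as `YYYYMMDD`.
#' @param scope_policy `"narrow_broad"` or `"narrow"`.
#' @param comparator `"rest_of_database"` or `"within_cohort"`.
#' @param alpha Two-sided level for intervals and the univariate screen.
#' @param min_case_count Screen threshold on exposed-with-event counts.
#' @param min_events Cascade threshold on events per drug cohort.
#' @param min_freq Display threshold for the frequency table.
#' @param age_test `"block"` or `"dummy"` univariate age-category test.
#' @param strict_io Raise on malformed input rows.
#' @param seed Integer seed (simulation only; the analysis itself is
#'   deterministic).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            smq_definitions = NULL, smq_terms = NULL,
                            lexicon = NULL,
                            indication_pts = default_indication_patterns(),
                            date_window = c(20150101L, 20250331L),
                            scope_policy = "narrow_broad",
                            comparator = "rest_of_database",
                            alpha = 0.05, min_case_count = 3L,
                            min_events = 60L, min_freq = 0.05,
                            age_test = "block", strict_io = FALSE,
                            seed = 1L) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0,1)")
  if (!dir.exists(input_dir)) stop("input_dir does not exist: ", input_dir)
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 smq_definitions = smq_definitions, smq_terms = smq_terms,
                 lexicon = lexicon, indication_pts = indication_pts,
                 date_window = as.integer(date_window),
                 scope_policy = scope_policy, comparator = comparator,
                 alpha = alpha, min_case_count = as.integer(min_case_count),
                 min_events = as.integer(min_events), min_freq = min_freq,
                 age_test = age_test, strict_io = strict_io,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full signal-detection pipeline
#'
#' Stage order is fixed: ingest, deduplicate, cohort construction, SMQ
#' mapping, disproportionality screen, univariate-to-multivariate cascade,
#' report. Every stage's input and output record counts are logged and
#' written to a machine-readable manifest; reruns with identical
#' configuration and inputs produce byte-identical outputs.
#'
#' Output files in `output_dir`: `cohort_summary.csv`, `exclusions.csv`,
#' `signal_screen.csv`, `smq_frequencies.csv`, `adjusted_or.csv`,
#' `manifest.json`, `run.log`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  counts <- list()

  bundle <- stage("ingest",
                  read_faers_bundle(config$input_dir, strict = config$strict_io))
  counts$ingest <- c(reports_in = nrow(bundle$demo))
  say("ingest: %d DEMO rows", nrow(bundle$demo))

  deduped <- stage("dedup", dedup_bundle(bundle))
  counts$dedup <- c(reports_in = nrow(bundle$demo),
                    cases_out = nrow(deduped$demo),
                    dropped = nrow(bundle$demo) - nrow(deduped$demo))
  say("dedup: kept %d of %d report versions (%d superseded dropped)",
      nrow(deduped$demo), nrow(bundle$demo),
      nrow(bundle$demo) - nrow(deduped$demo))

  lexicon <- stage("cohort", load_drug_lexicon(config$lexicon))
  cohort <- stage("cohort",
                  build_cohort(deduped, lexicon,
                               indication_pts = config$indication_pts,
                               date_window = config$date_window))
  counts$cohort <- c(cases_in = nrow(deduped$demo),
                     cases_out = nrow(cohort$cases),
                     unlist(cohort$exclusions[
                       setdiff(names(cohort$exclusions),
                               c("retained", "input"))]))
  say("cohort: retained %d of %d cases", nrow(cohort$cases),
      nrow(deduped$demo))

  dict <- stage("map", expand_smq_hierarchy(
    load_smq_dictionary(config$smq_definitions, config$smq_terms)))
  case_smqs <- stage("map", map_case_smqs(deduped$reac, dict,
                                          scope_policy = config$scope_policy))
  counts$map <- c(cases_in = nrow(cohort$cases),
                  flags = nrow(case_smqs),
                  unmapped_pts = length(attr(case_smqs, "unmapped")))
  say("map: %d case-SMQ flags over %d SMQs (%d unmapped PT names)",
      nrow(case_smqs), nrow(dict$smqs), length(attr(case_smqs, "unmapped")))

  screen <- stage("screen",
                  screen_signals(cohort$cases, deduped$demo$PRIMARYID,
                                 case_smqs, dict = dict,
                                 min_case_count = config$min_case_count,
                                 alpha = config$alpha,
                                 comparator = config$comparator))
  counts$screen <- c(pairs = nrow(screen),
                     signals = sum(screen$is_signal),
                     insufficient = sum(screen$status == "insufficient"))
  say("screen: %d drug-SMQ pairs, %d signals", nrow(screen),
      sum(screen$is_signal))

  freq <- stage("screen", frequency_table(cohort$cases, case_smqs,
                                          min_freq = config$min_freq,
                                          dict = dict))

  aor <- stage("regress",
               multivariate_cascade(cohort$cases, screen, case_smqs,
                                    min_events = config$min_events,
                                    alpha = config$alpha,
                                    age_test = config$age_test,
                                    dict = dict))
  counts$regress <- c(pairs_in = sum(screen$is_signal),
                      fitted = length(unique(aor[status == "ok",
                                                 paste(drug, smq_code)])),
                      skipped_min_events = length(unique(
                        aor[status == "min_events", paste(drug, smq_code)])))
  say("regress: fitted %d of %d signal pairs (min_events = %d)",
      counts$regress[["fitted"]], counts$regress[["pairs_in"]],
      config$min_events)

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(x) file.path(config$output_dir, x)
  summary_tab <- summarize_cohort(cohort$cases)
  data.table::fwrite(summary_tab, outfile("cohort_summary.csv"))
  excl <- data.table::data.table(reason = names(cohort$exclusions),
                                 n = unlist(cohort$exclusions))
  data.table::fwrite(excl, outfile("exclusions.csv"))
  data.table::fwrite(screen, outfile("signal_screen.csv"))
  data.table::fwrite(freq, outfile("smq_frequencies.csv"))
  data.table::fwrite(aor, outfile("adjusted_or.csv"))

  cfg_for_json <- config
  class(cfg_for_json) <- NULL
  cfg_json <- jsonlite::toJSON(cfg_for_json, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  config_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  manifest <- list(package = "faersage",
                   version = as.character(packageVersion("faersage")),
                   config = jsonlite::fromJSON(cfg_json),
                   config_hash = config_hash,
                   counts = counts)
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, outfile("run.log"))

  invisible(list(cohort = cohort, case_smqs = case_smqs, screen = screen,
                 frequencies = freq, adjusted_or = aor,
                 summary = summary_tab, manifest = manifest))
}
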