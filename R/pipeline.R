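# End-to-end driver: bundle -> mapping -> episodes -> eligibility ->
# assignments -> patterns -> reports, with a JSON run manifest. Stages are
# plain functions over tables, so each stage is independently testable and
# intermediate CSVs can be written for inspection.

#' Default pipeline configuration
#'
#' @param input_dir,output_dir Bundle and artifact directories.
#' @param mapping `"dictionary"` (product-code dictionary) or
#'   `"vocabulary"` (concept / concept_ancestor tables).
#' @param study_start,study_end Study window (defaults 2012-01-01 ..
#'   2020-12-31).
#' @param merge_gap_days Admission-merge threshold in days (default 30).
#' @param followup_days Post-discharge follow-up window (default 7).
#' @param followup_policy `"require-followup-data"` or `"keep-all"`.
#' @param excluded_atc2_patterns ATC2 classes excluded from pattern
#'   analyses (default `"B05"`).
#' @param excluded_atc2_counting ATC2 classes excluded before level
#'   determination (default none).
#' @param pattern_min_age Age floor for pattern analyses (default 65).
#' @param top_n Patterns kept per category (default 10).
#' @return Named list of class `polyrx_run_config`.
#' @export
run_config <- function(input_dir = ".", output_dir = ".",
                       mapping = c("dictionary", "vocabulary"),
                       study_start = "2012-01-01", study_end = "2020-12-31",
                       merge_gap_days = 30L, followup_days = 7L,
                       followup_policy = "require-followup-data",
                       excluded_atc2_patterns = "B05",
                       excluded_atc2_counting = character(),
                       pattern_min_age = 65L, top_n = 10L) {
  mapping <- match.arg(mapping)
  stopifnot(merge_gap_days >= 0L, followup_days >= 0L, top_n >= 1L)
  structure(list(
    input_dir = input_dir, output_dir = output_dir, mapping = mapping,
    study_start = study_start, study_end = study_end,
    merge_gap_days = as.integer(merge_gap_days),
    followup_days = as.integer(followup_days),
    followup_policy = followup_policy,
    excluded_atc2_patterns = excluded_atc2_patterns,
    excluded_atc2_counting = excluded_atc2_counting,
    pattern_min_age = as.integer(pattern_min_age),
    top_n = as.integer(top_n)
  ), class = "polyrx_run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; absent keys take defaults.
#'
#' @param path YAML file path.
#' @return A `polyrx_run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' Run the full polypharmacy characterization pipeline
#'
#' Reads a CDM bundle, maps drugs to ATC/ingredient codes, builds merged
#' admission episodes with follow-up, applies the eligibility policy,
#' assigns polypharmacy categories, mines single and combination ATC2
#' patterns for the older population, and produces the three report
#' shapes. When `config$output_dir` is set, writes `assignments.csv`,
#' `single_patterns.csv`, `combo_patterns.csv`, `table_summary.json`,
#' `table_stats.csv`, `table_distribution.csv`, and `manifest.json`.
#'
#' Pattern analyses exclude `excluded_atc2_patterns` (default B05) before
#' daily counting, so the maximum-count day used for combination keys is
#' determined on the excluded exposure set; level determination for the
#' distribution and summary tables uses `excluded_atc2_counting` (default
#' none).
#'
#' @param config A [run_config()].
#' @param bundle Optional pre-loaded bundle (list of tables); when `NULL`,
#'   read from `config$input_dir`.
#' @param write Write artifact files to `config$output_dir` (default TRUE
#'   when `output_dir` is set and exists or can be created).
#' @return Invisibly, a list with all intermediate and final tables plus
#'   the run `manifest`.
#' @export
run_pipeline <- function(config = run_config(), bundle = NULL, write = TRUE) {
  t0 <- Sys.time()
  if (is.null(bundle)) bundle <- read_bundle(config$input_dir)
  stage_counts <- list()
  warn <- character()
  note <- function(stage, n) stage_counts[[stage]] <<- n

  atc_map <- withCallingHandlers(
    if (config$mapping == "dictionary") {
      if (is.null(bundle$dictionary)) stop("mapping stage: no dictionary table")
      load_dictionary(bundle$dictionary)
    } else {
      if (is.null(bundle$concept) || is.null(bundle$concept_ancestor)) {
        stop("mapping stage: concept/concept_ancestor tables required")
      }
      derive_from_vocabulary(bundle$concept, bundle$concept_ancestor)
    },
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  note("atc_map_rows", nrow(atc_map))

  admissions <- extract_admissions(bundle$visit_occurrence,
                                   config$study_start, config$study_end)
  note("admissions", nrow(admissions))
  episodes <- attach_followup(merge_admissions(admissions,
                                               config$merge_gap_days),
                              config$followup_days)
  note("episodes", nrow(episodes))

  elig <- eligibility_filter(episodes, bundle$drug_exposure,
                             config$followup_policy)
  keep_ids <- elig[keep == TRUE, person_id]
  episodes <- episodes[person_id %in% keep_ids]
  note("patients_retained", length(keep_ids))
  note("patients_dropped", nrow(elig) - length(keep_ids))

  mp <- map_exposures(
    as.data.table(bundle$drug_exposure)[person_id %in% keep_ids], atc_map)
  note("mapped_exposure_rows", nrow(mp$exposures))
  note("unmapped_drug_codes", mp$report$n_unmapped)

  counting_exposures <- exclude_atc2(mp$exposures,
                                     config$excluded_atc2_counting)
  assignments <- assign_cohort(counting_exposures, episodes)
  note("assignments", nrow(assignments))

  ages <- cohort_ages(bundle$person, episodes)

  pattern_exposures <- exclude_atc2(mp$exposures,
                                    config$excluded_atc2_patterns)
  pattern_assignments <- assign_cohort(pattern_exposures, episodes)
  singles <- top_patterns(
    single_frequencies(pattern_exposures, pattern_assignments, ages,
                       episodes, config$pattern_min_age), config$top_n)
  combos <- top_patterns(
    combination_patterns(pattern_exposures, pattern_assignments, ages,
                         episodes, config$pattern_min_age), config$top_n)
  note("single_pattern_rows", nrow(singles))
  note("combo_pattern_rows", nrow(combos))

  summary_tbl <- cohort_summary(bundle$person, admissions, episodes,
                                mp$exposures, ages)
  stats_tbl <- summary_stats(assignments, episodes, ages)
  dist_tbl <- distribution_table(assignments, ages)

  manifest <- list(
    config = unclass(config),
    config_hash = config_hash(config),
    input_checksums = bundle_checksums(config$input_dir, bundle),
    stage_counts = stage_counts,
    mapping_report = mp$report[c("n_input_codes", "n_mapped", "n_unmapped")],
    warnings = warn,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  result <- list(atc_map = atc_map, admissions = admissions,
                 episodes = episodes, eligibility = elig,
                 mapped = mp$exposures, mapping_report = mp$report,
                 assignments = assignments, pattern_assignments =
                   pattern_assignments, ages = ages,
                 single_patterns = singles, combo_patterns = combos,
                 summary = summary_tbl, stats = stats_tbl,
                 distribution = dist_tbl, manifest = manifest)

  if (isTRUE(write) && !is.null(config$output_dir)) {
    od <- config$output_dir
    if (!dir.exists(od)) dir.create(od, recursive = TRUE)
    fwrite(assignments, file.path(od, "assignments.csv"))
    fwrite(singles, file.path(od, "single_patterns.csv"))
    fwrite(combos, file.path(od, "combo_patterns.csv"))
    fwrite(stats_tbl, file.path(od, "table_stats.csv"))
    fwrite(dist_tbl$formatted, file.path(od, "table_distribution.csv"))
    jsonlite::write_json(summary_tbl, file.path(od, "table_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(result)
}

# stable hash of the analytic configuration: md5 of its canonical JSON form,
# excluding the input/output locations so reruns elsewhere compare equal
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$input_dir <- NULL
  cfg$output_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

bundle_checksums <- function(input_dir, bundle) {
  files <- file.path(input_dir, paste0(names(bundle), ".csv"))
  present <- file.exists(files)
  if (!any(present)) return(list())
  sums <- tools::md5sum(files[present])
  as.list(setNames(unname(sums), basename(files[present])))
}
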