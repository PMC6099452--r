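# Pipeline orchestration: configuration, staged execution, artifact
# writing and a machine-readable run manifest. The pipeline itself draws
# no random numbers: for fixed inputs its outputs are identical across
# runs.

#' Pipeline configuration
#'
#' Bundles input paths and analysis parameters. File existence is checked
#' at run time by [run_pipeline()]. Combination products are resolved
#' patient-level (both classes) in the cohort/lines stages and aggregated
#' (non-metformin class only) in the national and geographic stages; the
#' convention is recorded in the manifest.
#'
#' @param prescriptions,clinical,demographics patient-level input CSVs.
#' @param pca,cpi,population,prevalence national-trend input CSVs
#'   (annual dispensing, price index, mid-year population, observed
#'   prevalence).
#' @param prescribing,practice_meta practice-level input CSVs.
#' @param output_dir directory for stage outputs and the manifest.
#' @param class_map_path drug class map CSV (default the shipped map).
#' @param gap_days episode stop-gap in days (default 183).
#' @param cpi_base_year CPI base year (default 2016).
#' @param window_months CCG aggregation window length (default 12).
#' @param min_practices_per_month decile-series threshold (default 10).
#' @param seed seed echoed into the manifest (the pipeline itself is
#'   deterministic; the seed documents how the inputs were generated).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(prescriptions, clinical, demographics,
                            pca, cpi, population, prevalence,
                            prescribing, practice_meta,
                            output_dir,
                            class_map_path = default_class_map_path(),
                            gap_days = DEFAULT_GAP_DAYS,
                            cpi_base_year = 2016,
                            window_months = 12,
                            min_practices_per_month = 10,
                            seed = NULL) {
  stopifnot(is.numeric(gap_days), gap_days > 0)
  stopifnot(window_months >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

config_input_paths <- function(config) {
  unlist(config[c("prescriptions", "clinical", "demographics", "pca", "cpi",
                  "population", "prevalence", "prescribing", "practice_meta",
                  "class_map_path")])
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage [", stage, "] failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured inputs and writes the artifacts
#' to `config$output_dir`: `cohort.csv`, `lines.csv`, `line_shares.csv`,
#' `episodes.csv`, `national_trends.csv`, `ccg_summary.csv`,
#' `decile_series.csv`, `savings.json` and `manifest.json`. The manifest
#' echoes the configuration (file basenames), seed and software version,
#' and reconciles row counts in/kept/rejected/filtered per stage. Any
#' stage error aborts with the stage name and context. Rerunning on the
#' same inputs produces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages (default `TRUE`).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- config_input_paths(config)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  stages <- list()
  outputs <- list()
  emit <- function(tbl, name) {
    readr::write_csv(tbl, file.path(config$output_dir, name))
    outputs[[name]] <<- nrow(tbl)
  }

  class_map <- with_stage("class_map", read_class_map(config$class_map_path))

  # -- cohort ----------------------------------------------------------------
  say("stage: cohort")
  cohort_out <- with_stage("cohort", {
    prescriptions <- read_prescriptions_csv(config$prescriptions)
    clinical <- read_clinical_csv(config$clinical)
    demographics <- read_demographics_csv(config$demographics)
    decisions <- ascertain_cohort(prescriptions, clinical, demographics)
    list(prescriptions = prescriptions, clinical = clinical,
         decisions = decisions,
         rejected = nrow(attr(prescriptions, "rejects")) +
           nrow(attr(clinical, "rejects")) + nrow(attr(demographics, "rejects")))
  })
  decisions <- cohort_out$decisions
  emit(decisions, "cohort.csv")
  stages$cohort <- list(
    rows_in = nrow(decisions), rows_kept = sum(decisions$included),
    rows_filtered = sum(!decisions$included), rows_rejected = cohort_out$rejected,
    excluded_by_reason = as.list(table(as.character(
      decisions$reason[!decisions$included]
    )))
  )

  # -- therapy lines ---------------------------------------------------------
  say("stage: lines")
  lines_out <- with_stage("lines", {
    included <- decisions$patient_id[decisions$included]
    rx <- dplyr::filter(cohort_out$prescriptions, .data$patient_id %in% included)
    starts <- detect_new_starts(rx, class_map)
    insulin_dates <- dplyr::summarise(
      dplyr::group_by(dplyr::filter(rx, .data$is_insulin), .data$patient_id),
      insulin_date = min_date(.data$date), .groups = "drop"
    )
    line_events <- assign_lines(starts, insulin_dates)
    list(rx = rx, starts = starts, line_events = line_events,
         shares = line_share_table(line_events),
         episodes = build_episodes(rx, class_map, gap_days = config$gap_days))
  })
  emit(dplyr::select(lines_out$line_events, -"calendar_year"), "lines.csv")
  emit(lines_out$shares, "line_shares.csv")
  emit(lines_out$episodes, "episodes.csv")
  stages$lines <- list(
    rows_in = nrow(lines_out$starts),
    rows_kept = nrow(lines_out$line_events),
    rows_filtered = nrow(lines_out$starts) - nrow(lines_out$line_events),
    rows_rejected = 0L
  )

  # -- national trends -------------------------------------------------------
  say("stage: trends")
  trends <- with_stage("trends", {
    pca <- read_pca_csv(config$pca)
    cpi <- read_cpi_csv(config$cpi)
    population <- read_population_csv(config$population)
    observed <- read_prevalence_csv(config$prevalence)
    prevalence <- extrapolate_prevalence(observed, sort(unique(pca$year)))
    tt <- trend_table(pca, cpi, population, prevalence, class_map,
                      base_year = config$cpi_base_year)
    list(pca = pca, table = tt,
         rejected = nrow(attr(pca, "rejects")),
         prevalence_fit_r2 = attr(prevalence, "fit_r2"))
  })
  emit(trends$table, "national_trends.csv")
  stages$trends <- list(
    rows_in = nrow(trends$pca), rows_kept = nrow(trends$pca),
    rows_filtered = 0L, rows_rejected = trends$rejected,
    prevalence_fit_r2 = trends$prevalence_fit_r2
  )

  # -- geographic variation --------------------------------------------------
  say("stage: geo")
  geo <- with_stage("geo", {
    rows <- read_prescribing_csv(config$prescribing)
    meta <- read_practice_meta_csv(config$practice_meta)
    kept <- filter_practices(rows, meta, quiet = TRUE)
    summaries <- ccg_summary(kept, meta, class_map,
                             window_months = config$window_months)
    shares <- practice_share_table(kept, class_map)
    deciles <- decile_series(shares, min_practices = config$min_practices_per_month)
    savings <- savings_at_decile(summaries)
    list(rows = rows, kept = kept, summaries = summaries, deciles = deciles,
         savings = savings, removed = attr(kept, "removed"),
         rejected = nrow(attr(rows, "rejects")))
  })
  emit(geo$summaries, "ccg_summary.csv")
  emit(geo$deciles, "decile_series.csv")
  jsonlite::write_json(
    c(geo$savings, list(percentile_method = "linear interpolation (type 7)")),
    file.path(config$output_dir, "savings.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  outputs[["savings.json"]] <- 1L
  stages$geo <- list(
    rows_in = nrow(geo$rows),
    rows_kept = nrow(geo$kept),
    rows_filtered = sum(geo$removed$n_rows),
    rows_rejected = geo$rejected
  )

  # -- manifest --------------------------------------------------------------
  manifest <- list(
    package = "rxlines",
    version = as.character(utils::packageVersion("rxlines")),
    seed = config$seed,
    config = c(
      lapply(as.list(config_input_paths(config)), basename),
      list(gap_days = config$gap_days,
           cpi_base_year = config$cpi_base_year,
           window_months = config$window_months,
           min_practices_per_month = config$min_practices_per_month,
           combination_mode_patient = "patient_level",
           combination_mode_aggregated = "aggregated",
           percentile_method = "linear interpolation (type 7)",
           kurtosis = "excess (moment formula)")
    ),
    stages = stages,
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  say("pipeline complete: ", config$output_dir)
  invisible(manifest)
}
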