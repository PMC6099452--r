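# Self-contained demonstration inputs: simulates a small cohort and
# practice landscape, constructs the national tables from the planted
# per-patient trajectory, writes every CSV dialect the pipeline reads,
# and returns a ready-to-run pipeline configuration.

#' Default consumer price index table (synthetic)
#'
#' A smooth synthetic index, ~2.2% annual inflation, base 2016 = 100. The
#' index series is an input to the analysis, not a constant; this table
#' exists so the demonstration pipeline is self-contained.
#'
#' @param years years to cover.
#' @param base_year base year with index 100.
#' @return tibble `year`, `index`.
#' @export
demo_cpi_table <- function(years = 1998:2016, base_year = 2016) {
  tibble::tibble(year = years, index = round(100 / 1.022^(base_year - years), 1))
}

#' Default mid-year population table (synthetic)
#'
#' Linear growth from 48.5m, ~350k/year — the scale of England's mid-year
#' population estimates.
#'
#' @param years years to cover.
#' @return tibble `year`, `population`.
#' @export
demo_population_table <- function(years = 1998:2016) {
  tibble::tibble(year = years, population = 48.5e6 + 350e3 * (years - 1998))
}

#' Default type 2 diabetes prevalence line (synthetic)
#'
#' An exactly linear prevalence series (2.8% in 2000, +0.22 points/year),
#' the shape of survey-based type 2 prevalence estimates. Because it is
#' exactly linear, straight-line extrapolation from the observed window
#' reproduces it without error.
#'
#' @param years years to cover.
#' @return tibble `year`, `prevalence`.
#' @export
demo_prevalence_table <- function(years = 1998:2016) {
  tibble::tibble(year = years, prevalence = 2.8 + 0.22 * (years - 2000))
}

#' Write a self-contained demonstration input set
#'
#' Simulates a patient-level cohort and a practice-level landscape at a
#' fixed seed, builds the national annual dispensing table from the
#' planted per-patient trajectory, and writes all input CSVs under
#' `dir/inputs`. Returns a [pipeline_config()] whose outputs go to
#' `dir/results`.
#'
#' @param dir target directory (created if needed).
#' @param seed integer seed for the simulations.
#' @param n_patients cohort size.
#' @param n_ccgs,practices_per_ccg practice landscape size.
#' @return a `pipeline_config`, with the two simulation outputs attached
#'   as attributes `cohort_sim` and `geo_sim`.
#' @export
write_demo_inputs <- function(dir, seed = 20180605, n_patients = 150,
                              n_ccgs = 10, practices_per_ccg = 4) {
  inputs <- file.path(dir, "inputs")
  dir.create(inputs, recursive = TRUE, showWarnings = FALSE)
  p <- function(name) file.path(inputs, name)

  sim <- simulate_cohort(cohort_sim_config(n_patients = n_patients, seed = seed))
  readr::write_csv(sim$prescriptions, p("prescriptions.csv"))
  readr::write_csv(sim$clinical, p("clinical.csv"))
  readr::write_csv(sim$demographics, p("demographics.csv"))

  years <- 1998:2016
  cpi <- demo_cpi_table(years)
  population <- demo_population_table(years)
  prevalence <- demo_prevalence_table(years)
  pca <- synthetic_pca_table(default_national_trajectory(), prevalence,
                             population, cpi)
  readr::write_csv(pca, p("pca.csv"))
  readr::write_csv(cpi, p("cpi.csv"))
  readr::write_csv(population, p("population.csv"))
  # the pipeline extrapolates from the observed window to the full span
  readr::write_csv(dplyr::filter(prevalence, .data$year %in% 2000:2013),
                   p("prevalence.csv"))

  geo <- simulate_geo(geo_sim_config(n_ccgs = n_ccgs,
                                     practices_per_ccg = practices_per_ccg,
                                     seed = seed + 1))
  write_prescribing_csv(geo$rows, p("prescribing.csv"))
  readr::write_csv(geo$meta, p("practice_meta.csv"))

  config <- pipeline_config(
    prescriptions = p("prescriptions.csv"),
    clinical = p("clinical.csv"),
    demographics = p("demographics.csv"),
    pca = p("pca.csv"),
    cpi = p("cpi.csv"),
    population = p("population.csv"),
    prevalence = p("prevalence.csv"),
    prescribing = p("prescribing.csv"),
    practice_meta = p("practice_meta.csv"),
    output_dir = file.path(dir, "results"),
    seed = seed
  )
  attr(config, "cohort_sim") <- sim
  attr(config, "geo_sim") <- geo
  config
}
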