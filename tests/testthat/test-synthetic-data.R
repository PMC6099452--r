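test_that("cohort simulation is byte-identical for a fixed seed", {
  a <- simulate_cohort(cohort_sim_config(n_patients = 80, seed = 5))
  b <- simulate_cohort(cohort_sim_config(n_patients = 80, seed = 5))
  expect_identical(a$prescriptions, b$prescriptions)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$lines, b$truth$lines)
  c2 <- simulate_cohort(cohort_sim_config(n_patients = 80, seed = 6))
  expect_false(identical(a$prescriptions, c2$prescriptions))
})

test_that("zero contamination means everyone is ascertained as included", {
  cfg <- cohort_sim_config(
    n_patients = 120, seed = 31,
    contamination = list(early_onset = 0, early_insulin = 0,
                         other_diabetes = 0, pcos = 0, no_evidence = 0)
  )
  sim <- simulate_cohort(cfg)
  dec <- ascertain_cohort(sim$prescriptions, sim$clinical, sim$demographics)
  expect_true(all(dec$included))
})

test_that("invalid configurations are rejected", {
  bad_eras <- default_line_transitions()
  bad_eras[[1]]$rows[2, ] <- bad_eras[[1]]$rows[2, ] * 2
  expect_error(cohort_sim_config(eras = bad_eras), "sum to 1")
  expect_error(
    cohort_sim_config(contamination = list(early_onset = 0.9, early_insulin = 0.9,
                                           other_diabetes = 0, pcos = 0,
                                           no_evidence = 0)),
    "less than 1"
  )
  expect_error(geo_sim_config(national_shares = c(metformin = 1)), "setequal|names")
  shares <- c(metformin = 0.5, sulphonylurea = 0.2, TZD = 0.1, DPP4 = 0.1,
              GLP1 = 0.05, SGLT2 = 0.05, other = 0.5)
  expect_error(geo_sim_config(national_shares = shares), "sum to 1")
})

test_that("the truth line mix is the exact enumeration of the sampling scheme", {
  cfg <- cohort_sim_config(n_patients = 10, seed = 1)
  mix <- line_mix_truth(cfg)
  sums <- dplyr::summarise(dplyr::group_by(mix, era, line), s = sum(share),
                           .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
  # independent check by brute-force Monte Carlo on one era's rows
  rows <- default_line_transitions()[[3]]$rows
  set.seed(99)
  n_mc <- 20000
  hits <- matrix(0, 4, ncol(rows), dimnames = dimnames(rows))
  reach <- numeric(4)
  for (i in seq_len(n_mc)) {
    used <- character()
    for (k in 1:4) {
      p <- rows[k, ]
      p[used] <- 0
      if (sum(p) <= 0) break
      cl <- sample(colnames(rows), 1, prob = p)
      used <- c(used, cl)
      hits[k, cl] <- hits[k, cl] + 1
      reach[k] <- reach[k] + 1
    }
  }
  mc <- sweep(hits, 1, reach, "/")
  truth3 <- dplyr::filter(mix, era == "2013-2016")
  for (r in seq_len(nrow(truth3))) {
    expect_lt(abs(mc[truth3$line[r], truth3$class[r]] - truth3$share[r]), 0.02)
  }
})

test_that("planted line events are exactly what the pipeline reconstructs", {
  sim <- simulate_cohort(cohort_sim_config(n_patients = 250, seed = 88))
  dec <- ascertain_cohort(sim$prescriptions, sim$clinical, sim$demographics)
  inc <- dec$patient_id[dec$included]
  rx <- dplyr::filter(sim$prescriptions, patient_id %in% inc)
  got <- dplyr::arrange(assign_lines(detect_new_starts(rx, CM)), patient_id, line)
  want <- dplyr::arrange(dplyr::filter(sim$truth$lines, patient_id %in% inc),
                         patient_id, line)
  expect_identical(got$patient_id, want$patient_id)
  expect_identical(got$class, want$class)
  expect_identical(got$line, want$line)
  expect_identical(got$start_date, want$start_date)
})

test_that("pipeline estimates of the planted mix tighten as n grows", {
  l1_err <- function(n, seed) {
    sim <- simulate_cohort(cohort_sim_config(n_patients = n, seed = seed))
    dec <- ascertain_cohort(sim$prescriptions, sim$clinical, sim$demographics)
    rx <- dplyr::filter(sim$prescriptions,
                        patient_id %in% dec$patient_id[dec$included])
    lv <- assign_lines(detect_new_starts(rx, CM))
    era <- sim$truth$inclusion[, c("patient_id", "era")]
    lv <- dplyr::inner_join(lv, era, by = "patient_id")
    est <- dplyr::mutate(
      dplyr::group_by(dplyr::count(lv, era, line, class), era, line),
      share = n / sum(n)
    )
    j <- dplyr::left_join(sim$truth$line_mix, dplyr::ungroup(est),
                          by = c("era", "line", "class"))
    j$share.y[is.na(j$share.y)] <- 0
    mean(abs(j$share.x - j$share.y))
  }
  expect_lt(l1_err(4000, 55), l1_err(320, 55))
})

test_that("geo simulation is reproducible and validates its configuration", {
  a <- simulate_geo(geo_sim_config(n_ccgs = 3, practices_per_ccg = 3, seed = 4))
  b <- simulate_geo(geo_sim_config(n_ccgs = 3, practices_per_ccg = 3, seed = 4))
  expect_identical(a$rows, b$rows)
  expect_identical(a$meta, b$meta)
  expect_error(geo_sim_config(unit_costs = c(
    metformin = 0, sulphonylurea = 5, TZD = 12, DPP4 = 40, GLP1 = 80,
    SGLT2 = 40, other = 10
  )), "positive")
})

test_that("zero dispersion makes every practice reproduce its CCG mix exactly", {
  geo <- simulate_geo(geo_sim_config(n_ccgs = 4, practices_per_ccg = 5, seed = 17,
                                     zero_dispersion = TRUE))
  shares <- practice_share_table(geo$rows, CM)
  planted <- geo$truth$ccg_shares_planted
  meta <- geo$meta
  shares$ccg_id <- meta$ccg_id[match(shares$practice_id, meta$practice_id)]
  j <- dplyr::inner_join(
    shares,
    tidyr::pivot_longer(planted, -ccg_id, names_to = "class",
                        values_to = "planted_share"),
    by = c("ccg_id", "class")
  )
  expect_true(all(abs(j$share_percent - j$planted_share) < 1e-9))
})

test_that("equal unit costs make cost shares equal item shares", {
  costs <- setNames(rep(10, 7), drug_class_labels())
  geo <- simulate_geo(geo_sim_config(n_ccgs = 3, practices_per_ccg = 4, seed = 23,
                                     unit_costs = costs))
  by_chem <- dplyr::mutate(
    geo$rows,
    class = classify_chemical(vapply(split_constituents(chemical), function(p) {
      if (length(p) == 2) p[!tolower(p) %in% "metformin hydrochloride"] else p
    }, character(1)), CM)
  )
  agg <- dplyr::summarise(dplyr::group_by(by_chem, class),
                          items = sum(items), cost = sum(actual_cost),
                          .groups = "drop")
  expect_equal(agg$items / sum(agg$items), agg$cost / sum(agg$cost),
               tolerance = 1e-12)
})

test_that("generator outputs pass the readers' validation with zero warnings", {
  sim <- simulate_cohort(cohort_sim_config(n_patients = 60, seed = 2))
  geo <- simulate_geo(geo_sim_config(n_ccgs = 2, practices_per_ccg = 3, seed = 2))
  td <- withr::local_tempdir()
  expect_no_warning({
    readr::write_csv(sim$prescriptions, file.path(td, "rx.csv"))
    rx <- read_prescriptions_csv(file.path(td, "rx.csv"))
    readr::write_csv(sim$clinical, file.path(td, "clin.csv"))
    clin <- read_clinical_csv(file.path(td, "clin.csv"))
    readr::write_csv(sim$demographics, file.path(td, "demo.csv"))
    demo <- read_demographics_csv(file.path(td, "demo.csv"))
    write_prescribing_csv(geo$rows, file.path(td, "presc.csv"))
    rows <- read_prescribing_csv(file.path(td, "presc.csv"))
    readr::write_csv(geo$meta, file.path(td, "meta.csv"))
    meta <- read_practice_meta_csv(file.path(td, "meta.csv"))
  })
  expect_identical(nrow(rx), nrow(sim$prescriptions))
  expect_identical(nrow(rows), nrow(geo$rows))
  expect_identical(nrow(attr(rx, "rejects")), 0L)
  expect_identical(nrow(attr(rows, "rejects")), 0L)
})
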