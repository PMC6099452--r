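mk_meta <- function(n = 10, ccg = "CCG001", list_size = 8000, prev = 6.5,
                    setting = 4L, status = "active") {
  tibble::tibble(
    practice_id = sprintf("PR%03d", seq_len(n)),
    ccg_id = rep_len(ccg, n),
    setting_code = rep_len(setting, n),
    status = rep_len(status, n),
    list_size_15plus = rep_len(list_size, n),
    qof_prevalence = rep_len(prev, n)
  )
}

mk_rows <- function(meta, items = 100, chemical = "metformin",
                    month = as.Date("2017-08-01"), cost = items * 4) {
  tibble::tibble(
    practice_id = meta$practice_id,
    month = month,
    chemical = chemical,
    items = rep_len(items, nrow(meta)),
    actual_cost = rep_len(cost, nrow(meta))
  )
}

test_that("practice filtering removes closed, dormant and non-GP settings", {
  meta <- mk_meta(10)
  meta$status[c(2, 5)] <- "closed"
  meta$status[7] <- "dormant"
  meta$setting_code[9] <- 9L
  rows <- mk_rows(meta)
  kept <- filter_practices(rows, meta, quiet = TRUE)
  expect_identical(nrow(kept), 6L)
  removed <- attr(kept, "removed")
  expect_identical(
    removed$n_practices[match(c("closed", "dormant", "non_gp_setting"),
                              removed$reason)],
    c(2L, 1L, 1L)
  )
  expect_message(filter_practices(rows, meta), "closed")
})

test_that("the diabetes denominator is a list-size-weighted prevalence product", {
  one <- mk_meta(1, list_size = 10000, prev = 6.5)
  expect_equal(diabetes_denominator(one)$n_patients, 650)
  two <- mk_meta(2, list_size = 5000, prev = c(4, 8))
  d <- diabetes_denominator(two)
  expect_equal(d$prevalence_percent, 6)
  expect_equal(d$n_patients, 600)
  # random table matches brute-force per-practice summation
  set.seed(42)
  rnd <- tibble::tibble(
    practice_id = sprintf("PR%03d", 1:30),
    ccg_id = sample(sprintf("CCG%03d", 1:5), 30, replace = TRUE),
    setting_code = 4L, status = "active",
    list_size_15plus = sample(2000:20000, 30),
    qof_prevalence = round(runif(30, 4, 9), 2)
  )
  got <- diabetes_denominator(rnd)
  brute <- vapply(sort(unique(rnd$ccg_id)), function(cc) {
    s <- 0
    for (i in seq_len(nrow(rnd))) {
      if (rnd$ccg_id[i] == cc) {
        s <- s + rnd$list_size_15plus[i] * rnd$qof_prevalence[i] / 100
      }
    }
    s
  }, numeric(1))
  expect_equal(got$n_patients, unname(brute[got$ccg_id]))
})

test_that("CCG summaries reproduce hand-computed shares and per-patient costs", {
  counts <- c(metformin = 550, sulphonylurea = 220, DPP4 = 140, TZD = 25,
              SGLT2 = 41, GLP1 = 24)
  chems <- c(metformin = "metformin", sulphonylurea = "gliclazide",
             DPP4 = "sitagliptin", TZD = "pioglitazone",
             SGLT2 = "dapagliflozin", GLP1 = "liraglutide")
  meta <- mk_meta(1, list_size = 20000, prev = 5) # 1000 patients
  rows <- tibble::tibble(
    practice_id = meta$practice_id,
    month = as.Date("2017-08-01"),
    chemical = unname(chems[names(counts)]),
    items = as.integer(counts),
    actual_cost = 130000 * counts / sum(counts)
  )
  cs <- ccg_summary(rows, meta, CM, window = as.Date("2017-08-01"))
  expect_equal(cs$share_metformin, 55)
  expect_equal(cs$share_sulphonylurea, 22)
  expect_equal(cs$share_DPP4, 14)
  expect_equal(cs$share_TZD, 2.5)
  expect_equal(cs$share_SGLT2, 4.1)
  expect_equal(cs$share_GLP1, 2.4)
  expect_equal(cs$share_non_met_non_su, 23)
  expect_equal(cs$cost_per_patient, 130)
  expect_equal(cs$n_patients, 1000)

  # additivity: splitting one practice's rows across two months changes nothing
  rows2 <- dplyr::bind_rows(
    dplyr::mutate(rows, items = items %/% 2, actual_cost = actual_cost / 2),
    dplyr::mutate(rows, items = items - items %/% 2, actual_cost = actual_cost / 2,
                  month = as.Date("2017-07-01"))
  )
  cs2 <- ccg_summary(rows2, meta, CM,
                     window = as.Date(c("2017-07-01", "2017-08-01")))
  for (col in grep("^share_", names(cs), value = TRUE)) {
    expect_equal(cs2[[col]], cs[[col]], info = col)
  }
  expect_equal(cs2$cost_per_patient, cs$cost_per_patient)
})

test_that("a CCG with zero antidiabetic items is excluded with a warning", {
  meta <- mk_meta(2, ccg = c("CCG001", "CCG002"))
  rows <- mk_rows(meta)
  rows$items[2] <- 0L
  rows$actual_cost[2] <- 0
  expect_warning(
    cs <- ccg_summary(rows, meta, CM, window = as.Date("2017-08-01")),
    "CCG002"
  )
  expect_identical(cs$ccg_id, "CCG001")
})

test_that("distribution stats use sample SD, type-7 quartiles and excess kurtosis", {
  d <- distribution_stats(c(1, 2, 3, 4))
  expect_equal(d$median, 2.5)
  expect_equal(d$iqr, 1.5)
  expect_equal(d$sd, sd(c(1, 2, 3, 4)))
  expect_error(distribution_stats(c(1, 2, 3)), "at least 4")
  expect_true(is.na(distribution_stats(rep(5, 10))$kurtosis))

  set.seed(314)
  z <- rnorm(1e5)
  expect_lt(abs(distribution_stats(z)$kurtosis), 0.05)

  heavy <- exp(rnorm(5000)) # log-normal: strongly leptokurtic
  k <- distribution_stats(heavy)$kurtosis
  expect_gt(k, 5)
  expect_equal(k, oracle_kurtosis(heavy), tolerance = 1e-12)
})

test_that("decile series interpolate order statistics and never cross", {
  shares <- tibble::tibble(
    practice_id = sprintf("PR%02d", 1:10),
    month = as.Date("2017-01-01"),
    class = "metformin",
    items = 1L,
    share_percent = seq(0, 90, by = 10)
  )
  ds <- decile_series(shares)
  expect_equal(ds$share_percent[ds$decile == 10], 9)
  expect_equal(ds$share_percent[ds$decile == 50], 45)
  expect_equal(ds$share_percent[ds$decile == 90], 81)
  expect_equal(ds$share_percent[ds$decile == 10], oracle_quantile7(shares$share_percent, 0.1))

  # identical practices give identical deciles
  same <- dplyr::mutate(shares, share_percent = 55)
  expect_true(all(decile_series(same)$share_percent == 55))

  # duplicating the median practice leaves the median unchanged
  dup <- dplyr::bind_rows(shares, dplyr::mutate(shares[shares$share_percent == 45, ],
                                                practice_id = "PR99"))
  expect_equal(decile_series(dup)$share_percent[ds$decile == 50], 45)

  # non-crossing within a month, on simulated data
  geo <- simulate_geo(geo_sim_config(n_ccgs = 4, practices_per_ccg = 5, seed = 9))
  kept <- filter_practices(geo$rows, geo$meta, quiet = TRUE)
  ds2 <- decile_series(practice_share_table(kept, CM))
  mono <- dplyr::summarise(
    dplyr::group_by(ds2, month, class),
    ok = all(diff(share_percent[order(decile)]) >= -1e-12), .groups = "drop"
  )
  expect_true(all(mono$ok))
})

test_that("months with too few practices are skipped with a warning", {
  shares <- tibble::tibble(
    practice_id = sprintf("PR%02d", c(1:10, 1:3)),
    month = as.Date(c(rep("2017-01-01", 10), rep("2017-02-01", 3))),
    class = "metformin", items = 1L,
    share_percent = c(seq(0, 90, 10), 50, 55, 60)
  )
  expect_warning(ds <- decile_series(shares), "2017-02")
  expect_false(as.Date("2017-02-01") %in% ds$month)
})

test_that("lowest-decile savings match the brute-force oracle", {
  flat <- tibble::tibble(cost_per_patient = rep(130, 12), n_patients = 1000)
  expect_equal(savings_at_decile(flat)$total_saving, 0)

  ten <- tibble::tibble(cost_per_patient = seq(95, 185, by = 10),
                        n_patients = rep(1000, 10))
  got <- savings_at_decile(ten)
  want <- oracle_savings(ten$cost_per_patient, ten$n_patients)
  expect_equal(got$benchmark_cost_per_patient, want$benchmark)
  expect_equal(got$total_saving, want$saving)
  expect_equal(got$saving_fraction, want$saving / sum(ten$cost_per_patient * 1000))

  set.seed(2718)
  for (i in 1:20) {
    n_ccg <- sample(10:40, 1)
    tbl <- tibble::tibble(
      cost_per_patient = runif(n_ccg, 60, 200),
      n_patients = runif(n_ccg, 500, 30000)
    )
    got <- savings_at_decile(tbl)
    want <- oracle_savings(tbl$cost_per_patient, tbl$n_patients)
    expect_equal(got$total_saving, want$saving)
    # the benchmark is an order statistic below the median
    expect_lte(got$benchmark_cost_per_patient, median(tbl$cost_per_patient))
  }
  expect_error(savings_at_decile(ten[1:5, ]), "at least 10")
})

test_that("savings shift consistently when all costs move by a constant", {
  set.seed(4)
  tbl <- tibble::tibble(cost_per_patient = runif(25, 60, 200),
                        n_patients = runif(25, 500, 30000))
  base <- savings_at_decile(tbl)
  shifted <- savings_at_decile(dplyr::mutate(tbl, cost_per_patient = cost_per_patient + 17))
  # adding a constant to every cost moves the benchmark by the same constant
  expect_equal(shifted$benchmark_cost_per_patient,
               base$benchmark_cost_per_patient + 17)
  # and leaves every above-benchmark excess unchanged
  expect_equal(shifted$total_saving, base$total_saving)
})

test_that("between-CCG spread of DPP-4 share is recovered at 200 CCGs", {
  geo <- simulate_geo(geo_sim_config(n_ccgs = 200, practices_per_ccg = 2,
                                     seed = 1234, prop_closed = 0,
                                     prop_dormant = 0, prop_non_gp = 0))
  kept <- filter_practices(geo$rows, geo$meta, quiet = TRUE)
  cs <- ccg_summary(kept, geo$meta, CM)
  planted_sd <- sd(geo$truth$ccg_shares_planted$DPP4)
  recovered_sd <- distribution_stats(cs$share_DPP4)$sd
  expect_lt(abs(recovered_sd - planted_sd) / planted_sd, 0.15)
})
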