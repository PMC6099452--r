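test_that("first-ever class starts ignore repeats and honour combinations", {
  rx <- rx_tbl(rep("A", 3), c("2005-02-01", "2006-02-01", "2008-02-01"),
               c("metformin", "metformin", "gliclazide"))
  st <- detect_new_starts(rx, CM)
  expect_identical(st$class, c("metformin", "sulphonylurea"))
  expect_identical(st$date, as.Date(c("2005-02-01", "2008-02-01")))

  combo <- rx_tbl("B", "2010-05-01", "Metformin Hydrochloride/Sitagliptin")
  st2 <- detect_new_starts(combo, CM)
  expect_setequal(st2$class, c("metformin", "DPP4"))
  expect_identical(unique(st2$date), as.Date("2010-05-01"))
})

test_that("start detection is invariant to input row order", {
  rx <- rx_tbl(rep("A", 2), c("2008-01-01", "2005-01-01"),
               c("gliclazide", "metformin"))
  expect_identical(detect_new_starts(rx, CM), detect_new_starts(rx[2:1, ], CM))
})

test_that("episodes split on gaps of at least 183 days", {
  mk <- function(days) rx_tbl(rep("A", length(days)),
                              format(as.Date("2010-01-01") + days), "metformin")
  e1 <- build_episodes(mk(c(0, 60, 120, 400)), CM)
  expect_identical(nrow(e1), 2L)
  expect_identical(as.numeric(e1$end_date[1] - e1$start_date[1]), 120)
  expect_false(e1$open[1])
  expect_true(e1$open[2])
  expect_identical(e1$start_date[2], as.Date("2010-01-01") + 400)

  expect_identical(nrow(build_episodes(mk(c(0, 182)), CM)), 1L)
  expect_identical(nrow(build_episodes(mk(c(0, 183)), CM)), 2L) # boundary: >= 183 splits
})

test_that("episode boundary behaviour matches a brute-force gap splitter", {
  set.seed(77)
  for (rep in 1:50) {
    days <- sort(sample(0:900, sample(2:8, 1)))
    rx <- rx_tbl(rep("A", length(days)), format(as.Date("2010-01-01") + days),
                 "metformin")
    got <- build_episodes(rx, CM)
    want <- oracle_episodes(as.Date("2010-01-01") + days, 183)
    expect_identical(got$start_date, want$start_date)
    expect_identical(got$end_date, want$end_date)
  }
})

test_that("episode segmentation ignores duplicate same-day prescriptions", {
  days <- c(0, 0, 100, 100, 300)
  rx <- rx_tbl(rep("A", length(days)), format(as.Date("2010-01-01") + days),
               "metformin")
  dedup <- rx[!duplicated(rx$date), ]
  expect_identical(
    build_episodes(rx, CM)[c("start_date", "end_date")],
    build_episodes(dedup, CM)[c("start_date", "end_date")]
  )
})

test_that("lines are numbered in start order, capped at four", {
  st <- tibble::tibble(
    patient_id = "A",
    class = c("metformin", "sulphonylurea", "DPP4"),
    date = as.Date(c("2005-01-01", "2008-01-01", "2012-01-01"))
  )
  lv <- assign_lines(st)
  expect_identical(lv$line, 1:3)
  expect_identical(lv$calendar_year, c(2005L, 2008L, 2012L))

  five <- tibble::tibble(
    patient_id = "B",
    class = c("metformin", "sulphonylurea", "DPP4", "SGLT2", "GLP1"),
    date = as.Date("2005-01-01") + (0:4) * 200
  )
  expect_identical(nrow(assign_lines(five)), 4L)
  expect_false("GLP1" %in% assign_lines(five)$class)
})

test_that("same-date ties give metformin the lower line, then alphabetical", {
  st <- tibble::tibble(
    patient_id = "A", class = c("DPP4", "metformin"),
    date = as.Date(c("2010-01-01", "2010-01-01"))
  )
  lv <- assign_lines(st)
  expect_identical(lv$class[lv$line == 1], "metformin")
  st2 <- tibble::tibble(
    patient_id = "A", class = c("sulphonylurea", "DPP4"),
    date = as.Date(c("2010-01-01", "2010-01-01"))
  )
  expect_identical(assign_lines(st2)$class, c("DPP4", "sulphonylurea"))
})

test_that("starts on or after the first insulin date are dropped", {
  st <- tibble::tibble(
    patient_id = "A", class = c("metformin", "DPP4", "SGLT2"),
    date = as.Date(c("2005-01-01", "2010-01-01", "2012-01-01"))
  )
  ins <- tibble::tibble(patient_id = "A", insulin_date = as.Date("2010-01-01"))
  lv <- assign_lines(st, ins)
  expect_identical(lv$class, "metformin")
})

test_that("line assignment matches the brute-force sequencer on random histories", {
  set.seed(99)
  rx <- dplyr::bind_rows(lapply(1:100, function(i) random_history(sprintf("P%03d", i))))
  got <- assign_lines(detect_new_starts(rx, CM))
  want <- oracle_lines(rx, CM)
  expect_identical(got$patient_id, want$patient_id)
  expect_identical(got$class, want$class)
  expect_identical(got$line, want$line)
  expect_identical(got$start_date, want$date)
})

test_that("line share tables are percentages summing to 100 per (year, line)", {
  ev <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    class = c("sulphonylurea", "sulphonylurea", "DPP4", "DPP4"),
    line = 2L, start_date = as.Date("2016-06-01"), calendar_year = 2016L
  )
  tab <- line_share_table(ev)
  expect_identical(tab$percent, c(50, 50))

  single <- line_share_table(ev[1, ])
  expect_identical(single$percent, 100)

  sim <- simulate_cohort(cohort_sim_config(n_patients = 400, seed = 21))
  dec <- ascertain_cohort(sim$prescriptions, sim$clinical, sim$demographics)
  rx <- dplyr::filter(sim$prescriptions, patient_id %in%
                        dec$patient_id[dec$included])
  tab2 <- line_share_table(assign_lines(detect_new_starts(rx, CM)))
  sums <- dplyr::summarise(dplyr::group_by(tab2, calendar_year, line),
                           s = sum(percent), .groups = "drop")
  expect_true(all(abs(sums$s - 100) < 1e-9))
})

test_that("patients with a line-k event are non-increasing in k", {
  sim <- simulate_cohort(cohort_sim_config(n_patients = 600, seed = 13))
  dec <- ascertain_cohort(sim$prescriptions, sim$clinical, sim$demographics)
  rx <- dplyr::filter(sim$prescriptions, patient_id %in%
                        dec$patient_id[dec$included])
  lv <- assign_lines(detect_new_starts(rx, CM))
  counts <- table(factor(lv$line, levels = 1:4))
  expect_true(all(diff(as.integer(counts)) <= 0))
})
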