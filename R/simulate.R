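# Synthetic data generators with known ground truth.
#
# Two generators emulate the structures the pipeline consumes: a
# patient-level cohort (prescriptions, clinical events, demographics) with
# planted line-of-therapy class mixes and planted cohort contamination, and
# a practice-level dispensing table with planted CCG class mixes, costs and
# practice filtering targets. A helper constructs an annual national
# dispensing table from a planted per-patient trajectory. A single seed per
# generator governs all randomness.

STUDY_END <- as.Date("2016-12-31")

# -- small numeric helpers ---------------------------------------------------

# Dirichlet draws via the gamma construction (no installed package provides
# one); rows sum to 1.
rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  sw <- sweep(g, 1, rowSums(g), "/")
  colnames(sw) <- names(alpha)
  sw
}

# integer allocation of `total` across cells proportional to `w`
# (largest-remainder method, so the parts always sum to `total`)
largest_remainder <- function(w, total) {
  if (total == 0 || sum(w) == 0) return(integer(length(w)))
  exact <- w / sum(w) * total
  base <- floor(exact)
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# round a probability vector to thousandths that still sum to exactly 1
round_to_thousandths <- function(p) largest_remainder(p, 1000L) / 1000

# row-wise largest remainder: allocate each element of `totals` across
# cells proportional to `w`; returns a length(totals) x length(w) matrix
# whose rows sum to `totals`
row_largest_remainder <- function(totals, w) {
  if (length(w) == 1) return(matrix(totals, ncol = 1))
  exact <- outer(totals, w / sum(w))
  base <- floor(exact)
  short <- as.integer(round(totals - rowSums(base)))
  rem <- exact - base
  rk <- t(apply(-rem, 1, rank, ties.method = "first"))
  base + (rk <= short)
}

#' First-of-month sequence
#'
#' @param end last month, `"YYYY-MM"`.
#' @param n number of months.
#' @return Date vector of month starts, ascending.
#' @export
month_seq <- function(end = "2017-08", n = 12) {
  last <- as.Date(paste0(end, "-01"))
  sort(seq(last, by = "-1 month", length.out = n))
}

# -- cohort generator --------------------------------------------------------

# chemicals issued per class in the patient-level generator
CLASS_CHEMICALS <- list(
  metformin = c("Metformin Hydrochloride"),
  sulphonylurea = c("Gliclazide", "Glimepiride"),
  TZD = c("Pioglitazone", "Rosiglitazone Maleate"),
  DPP4 = c("Sitagliptin", "Linagliptin"),
  GLP1 = c("Liraglutide", "Exenatide"),
  SGLT2 = c("Dapagliflozin", "Empagliflozin"),
  other = c("Acarbose", "Repaglinide")
)

line_row <- function(...) {
  v <- c(...)
  out <- setNames(numeric(length(ALL_CLASSES)), ALL_CLASSES)
  out[names(v)] <- v
  out
}

#' Default per-era line-transition rows
#'
#' Three prescribing eras keyed to the patient's diagnosis year, each with
#' one class-probability row per therapy line (1-4). Rows are conditional
#' sampling rows: when a patient reaches line k, the classes they have
#' already started are removed and the row renormalised (a class can start
#' at most once per patient). The early era is sulphonylurea/TZD
#' dominated, the middle era sees gliptins arrive, and the recent era
#' carries the modern second-line mix (DPP-4 0.43, sulphonylurea 0.34,
#' SGLT-2 0.14, remainder 0.09) with SGLT-2 inhibitors dominating fourth
#' line.
#'
#' @return list of eras, each `list(name, years, rows)` with a 4 x 7
#'   probability matrix.
#' @export
default_line_transitions <- function() {
  m <- function(r1, r2, r3, r4) {
    out <- rbind(r1, r2, r3, r4)
    rownames(out) <- paste0("line", 1:4)
    out
  }
  list(
    list(
      name = "1998-2006", years = 1998:2006,
      rows = m(
        line_row(metformin = 0.60, sulphonylurea = 0.35, other = 0.05),
        line_row(metformin = 0.25, sulphonylurea = 0.45, TZD = 0.20, other = 0.10),
        line_row(metformin = 0.15, sulphonylurea = 0.25, TZD = 0.45, other = 0.15),
        line_row(metformin = 0.15, sulphonylurea = 0.30, TZD = 0.35, other = 0.20)
      )
    ),
    list(
      name = "2007-2012", years = 2007:2012,
      rows = m(
        line_row(metformin = 0.90, sulphonylurea = 0.08, other = 0.02),
        line_row(metformin = 0.05, sulphonylurea = 0.50, TZD = 0.15, DPP4 = 0.25,
                 GLP1 = 0.03, other = 0.02),
        line_row(metformin = 0.05, sulphonylurea = 0.15, TZD = 0.12, DPP4 = 0.55,
                 GLP1 = 0.10, other = 0.03),
        line_row(metformin = 0.05, sulphonylurea = 0.15, TZD = 0.10, DPP4 = 0.30,
                 GLP1 = 0.35, other = 0.05)
      )
    ),
    list(
      name = "2013-2016", years = 2013:2016,
      rows = m(
        line_row(metformin = 0.91, sulphonylurea = 0.07, other = 0.02),
        line_row(metformin = 0.01, sulphonylurea = 0.34, TZD = 0.05, DPP4 = 0.43,
                 GLP1 = 0.02, SGLT2 = 0.14, other = 0.01),
        line_row(sulphonylurea = 0.10, TZD = 0.05, DPP4 = 0.40, GLP1 = 0.15,
                 SGLT2 = 0.27, other = 0.03),
        line_row(sulphonylurea = 0.08, TZD = 0.05, DPP4 = 0.15, GLP1 = 0.25,
                 SGLT2 = 0.45, other = 0.02)
      )
    )
  )
}

#' Cohort simulation configuration
#'
#' Defaults describe a plausible primary-care type 2 diabetes cohort:
#' diagnosis years spread over 1998-2016 with a mild upward ramp, age at
#' diagnosis centred on 62 years, roughly 28-day prescription intervals
#' (so the 183-day stop rule only triggers on planted discontinuations),
#' planted per-era line-transition rows, and small planted contamination
#' fractions exercising every exclusion path.
#'
#' @param n_patients number of patients.
#' @param seed integer RNG seed.
#' @param diagnosis_years candidate diagnosis years.
#' @param diagnosis_year_probs sampling weights over `diagnosis_years`
#'   (default a linear ramp).
#' @param age_mean,age_sd,age_min,age_max age-at-diagnosis distribution
#'   (truncated normal) for non-contaminated patients.
#' @param eras per-era line-transition rows, see
#'   [default_line_transitions()].
#' @param continuation_probs probability of reaching line k+1 given line k
#'   (length 3).
#' @param median_intensify_months median months between consecutive line
#'   starts (length 3, exponential waiting times).
#' @param rx_interval_days days between consecutive issues of one drug.
#' @param n_issues_mean mean number of issues per (patient, class).
#' @param discontinuation_prob probability a (patient, class) history
#'   contains a planted stop-gap of at least 183 days.
#' @param combination_prob probability a non-metformin line start in a
#'   patient already on metformin is issued as a combination product.
#' @param contamination named list of planted contamination rates:
#'   `early_onset` (age at diagnosis < 35), `early_insulin` (insulin
#'   within 12 months), `other_diabetes`, `pcos`, `no_evidence` (no
#'   qualifying diabetes evidence at all).
#' @param late_insulin_prob fraction of clean patients receiving insulin
#'   well after their final line start (>12 months after diagnosis; does
#'   not exclude).
#' @return a `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_patients = 1000, seed = 1L,
                              diagnosis_years = 1998:2016,
                              diagnosis_year_probs = NULL,
                              age_mean = 62, age_sd = 11,
                              age_min = 36, age_max = 90,
                              eras = default_line_transitions(),
                              continuation_probs = c(0.65, 0.46, 0.33),
                              median_intensify_months = c(30, 27, 21),
                              rx_interval_days = 28,
                              n_issues_mean = 10,
                              discontinuation_prob = 0.10,
                              combination_prob = 0.10,
                              contamination = list(
                                early_onset = 0.04, early_insulin = 0.04,
                                other_diabetes = 0.02, pcos = 0.02,
                                no_evidence = 0.01
                              ),
                              late_insulin_prob = 0.08) {
  if (is.null(diagnosis_year_probs)) {
    diagnosis_year_probs <- seq(1, 2, length.out = length(diagnosis_years))
  }
  stopifnot(length(diagnosis_year_probs) == length(diagnosis_years))
  for (era in eras) {
    rows <- era$rows
    if (!is.matrix(rows) || nrow(rows) != 4 || ncol(rows) != length(ALL_CLASSES) ||
        !identical(colnames(rows), ALL_CLASSES)) {
      stop("era '", era$name, "': rows must be a 4 x ", length(ALL_CLASSES),
           " matrix with class columns ", paste(ALL_CLASSES, collapse = ", "))
    }
    if (any(rows < 0) || any(abs(rowSums(rows) - 1) > 1e-8)) {
      stop("era '", era$name, "': class probability rows must be non-negative and sum to 1")
    }
  }
  era_years <- unlist(lapply(eras, `[[`, "years"))
  if (anyDuplicated(era_years) || !all(diagnosis_years %in% era_years)) {
    stop("era year ranges must be disjoint and cover all diagnosis years")
  }
  rates <- unlist(contamination)
  if (any(rates < 0) || sum(rates) >= 1) {
    stop("contamination rates must be non-negative and sum to less than 1")
  }
  structure(as.list(environment()), class = "cohort_sim_config")
}

# exact induced per-line class marginals for one era's conditional rows,
# computed by enumeration over distinct-class sequences
induced_line_mix <- function(rows) {
  k_max <- nrow(rows)
  res <- matrix(0, k_max, ncol(rows), dimnames = dimnames(rows))
  recurse <- function(prefix, w, k) {
    p <- rows[k, ]
    p[prefix] <- 0
    s <- sum(p)
    if (s <= 0) return()
    p <- p / s
    for (cl in colnames(rows)[p > 0]) {
      res[k, cl] <<- res[k, cl] + w * p[[cl]]
      if (k < k_max) recurse(c(prefix, cl), w * p[[cl]], k + 1)
    }
  }
  recurse(character(), 1, 1)
  sweep(res, 1, rowSums(res), "/")
}

#' Exact planted line-class mix of a cohort configuration
#'
#' The class-probability rows in a [cohort_sim_config()] are conditional:
#' classes already started by a patient are removed and the row
#' renormalised before sampling. This function returns the exact marginal
#' class distribution per (era, line) induced by that sampling scheme,
#' computed by enumeration over all distinct-class sequences — the ground
#' truth that pipeline estimates should recover.
#'
#' @param config a `cohort_sim_config`.
#' @return tibble `era`, `line`, `class`, `share` (probability; shares sum
#'   to 1 within each era and line).
#' @export
line_mix_truth <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  out <- lapply(config$eras, function(era) {
    mix <- induced_line_mix(era$rows)
    grid <- expand.grid(line = seq_len(nrow(mix)), class = colnames(mix),
                        stringsAsFactors = FALSE)
    tibble::tibble(
      era = era$name, line = as.integer(grid$line), class = grid$class,
      share = mix[cbind(grid$line, match(grid$class, colnames(mix)))]
    )
  })
  dplyr::filter(dplyr::bind_rows(out), .data$share > 0)
}

#' Simulate a patient-level cohort with known ground truth
#'
#' Generates date-ordered prescription and clinical event tables plus a
#' demographics roster, together with the planted truth: exact per-(era,
#' line) class mixes (see [line_mix_truth()]), per-patient inclusion
#' labels with expected exclusion reasons, and the planted line events.
#' Reproducible for a fixed seed. Records exercise every exclusion path
#' and every drug class, including combination products.
#'
#' @param config a [cohort_sim_config()].
#' @return list with `prescriptions`, `clinical`, `demographics`, `truth`
#'   (list of `line_mix`, `inclusion`, `lines`) and `config`.
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%05d", seq_len(n))

  rates <- unlist(config$contamination)
  label <- sample(c("clean", names(rates)), n, replace = TRUE,
                  prob = c(1 - sum(rates), rates))
  dx_year <- sample(config$diagnosis_years, n, replace = TRUE,
                    prob = config$diagnosis_year_probs)
  dx_date <- as.Date(paste0(dx_year, "-01-01")) + sample(0:364, n, replace = TRUE)
  age <- pmin(pmax(round(rnorm(n, config$age_mean, config$age_sd)),
                   config$age_min), config$age_max)
  age[label == "early_onset"] <- sample(20:34, sum(label == "early_onset"),
                                        replace = TRUE)
  birth_year <- dx_year - age

  era_of_year <- integer(max(config$diagnosis_years))
  for (i in seq_along(config$eras)) era_of_year[config$eras[[i]]$years] <- i
  era_idx <- era_of_year[dx_year]
  era_name <- vapply(config$eras, `[[`, character(1), "name")[era_idx]

  # number of lines each patient would reach (0 for the no-evidence planted
  # contaminants, who never receive an oral drug)
  cp <- config$continuation_probs
  u <- matrix(runif(n * 3), n)
  n_lines <- 1L + (u[, 1] < cp[1]) +
    (u[, 1] < cp[1] & u[, 2] < cp[2]) +
    (u[, 1] < cp[1] & u[, 2] < cp[2] & u[, 3] < cp[3])
  n_lines[label == "no_evidence"] <- 0L

  # class sequences: conditional renormalised draws from the era rows
  seq_class <- vector("list", n)
  for (i in seq_len(n)) {
    if (n_lines[i] == 0) next
    rows <- config$eras[[era_idx[i]]]$rows
    used <- character()
    for (k in seq_len(n_lines[i])) {
      p <- rows[k, ]
      p[used] <- 0
      if (sum(p) <= 0) break
      used <- c(used, sample(ALL_CLASSES, 1, prob = p))
    }
    seq_class[[i]] <- used
  }
  n_lines <- lengths(seq_class)

  # line start dates: diagnosis date, then exponential intensification gaps
  med_days <- config$median_intensify_months * 30.44
  events <- vector("list", n)
  for (i in seq_len(n)) {
    if (n_lines[i] == 0) next
    gaps <- if (n_lines[i] > 1) {
      pmax(1, round(rexp(n_lines[i] - 1, rate = log(2) / med_days[seq_len(n_lines[i] - 1)])))
    } else numeric(0)
    starts <- dx_date[i] + cumsum(c(0, gaps))
    keep <- starts <= STUDY_END
    if (!any(keep)) next
    events[[i]] <- tibble::tibble(
      patient_id = ids[i], era = era_name[i],
      class = seq_class[[i]][keep], line = seq_along(seq_class[[i]])[keep],
      start_date = starts[keep]
    )
  }
  lines_truth <- dplyr::bind_rows(events)

  # expand line events into prescription issues
  ev <- lines_truth
  ev$n_iss <- 1L + rpois(nrow(ev), config$n_issues_mean - 1)
  ev$disc <- runif(nrow(ev)) < config$discontinuation_prob & ev$n_iss >= 3
  ev$disc_after <- ifelse(ev$disc, 1L + floor(runif(nrow(ev)) * (ev$n_iss - 1L)), 0L)
  ev$disc_gap <- ifelse(ev$disc, 183L + floor(runif(nrow(ev)) * 120L), 0L)
  chem_pool <- CLASS_CHEMICALS
  ev$chemical <- vapply(ev$class, function(cl) {
    pool <- chem_pool[[cl]]
    pool[sample.int(length(pool), 1)]
  }, character(1))
  has_met_before <- ev$class != "metformin" & ev$line > 1 &
    ave(ev$class == "metformin", ev$patient_id, FUN = cumsum) -
      (ev$class == "metformin") > 0
  ev$combo <- has_met_before & runif(nrow(ev)) < config$combination_prob

  idx <- rep(seq_len(nrow(ev)), ev$n_iss)
  issue <- sequence(ev$n_iss)
  extra <- ifelse(ev$disc[idx] & issue > ev$disc_after[idx], ev$disc_gap[idx], 0)
  rx_date <- ev$start_date[idx] + (issue - 1) * config$rx_interval_days + extra
  is_combo_issue <- ev$combo[idx] & issue == 1
  drug_name <- ifelse(is_combo_issue,
                      paste0("Metformin Hydrochloride/", ev$chemical[idx]),
                      ev$chemical[idx])
  constituents <- ifelse(is_combo_issue,
                         paste0("metformin hydrochloride;", ev$chemical[idx]),
                         ev$chemical[idx])
  keep <- rx_date <= STUDY_END
  prescriptions <- tibble::tibble(
    patient_id = ev$patient_id[idx][keep],
    date = rx_date[keep],
    drug_name = drug_name[keep],
    constituents = constituents[keep],
    is_insulin = FALSE
  )

  # insulin: planted early-insulin contamination, plus late (harmless)
  # insulin for a fraction of clean patients
  early <- which(label == "early_insulin" & n_lines > 0)
  ins_early <- tibble::tibble(
    patient_id = ids[early],
    date = dx_date[early] +
      floor(runif(length(early)) *
              (pmin(365, as.numeric(STUDY_END - dx_date[early])) + 1))
  )
  last_start <- dplyr::summarise(
    dplyr::group_by(lines_truth, .data$patient_id),
    last = max(.data$start_date), .groups = "drop"
  )
  clean_ids <- ids[label == "clean" & n_lines > 0]
  late_pool <- last_start[last_start$patient_id %in% clean_ids, ]
  late_sel <- runif(nrow(late_pool)) < config$late_insulin_prob
  ins_late <- tibble::tibble(
    patient_id = late_pool$patient_id[late_sel],
    date = late_pool$last[late_sel] + 366 + sample(0:300, sum(late_sel), replace = TRUE)
  )
  ins_late <- dplyr::filter(ins_late, .data$date <= STUDY_END)
  insulin <- dplyr::bind_rows(ins_early, ins_late)
  if (nrow(insulin) > 0) {
    insulin$drug_name <- "Insulin Glargine"
    insulin$constituents <- "insulin glargine"
    insulin$is_insulin <- TRUE
    prescriptions <- dplyr::bind_rows(prescriptions, insulin)
  }
  prescriptions <- dplyr::arrange(prescriptions, .data$patient_id, .data$date,
                                  .data$drug_name)

  # clinical events
  with_dx_code <- n_lines > 0 & runif(n) < 0.7
  clin_dx <- tibble::tibble(
    patient_id = ids[with_dx_code], date = dx_date[with_dx_code],
    kind = "diabetes_dx_code", value = NA_real_
  )
  with_hba1c <- n_lines > 0 & runif(n) < 0.6
  clin_hb <- tibble::tibble(
    patient_id = ids[with_hba1c],
    date = pmin(dx_date[with_hba1c] + sample(0:60, sum(with_hba1c), replace = TRUE),
                STUDY_END),
    kind = "hba1c",
    value = round(runif(sum(with_hba1c), 48, 95), 1)
  )
  with_pre <- n_lines > 0 & runif(n) < 0.3
  clin_pre <- tibble::tibble(
    patient_id = ids[with_pre],
    date = dx_date[with_pre] - sample(100:400, sum(with_pre), replace = TRUE),
    kind = "hba1c",
    value = round(runif(sum(with_pre), 40, 47.4), 1)
  )
  noev <- which(label == "no_evidence")
  clin_noev <- tibble::tibble(
    patient_id = ids[noev],
    date = dx_date[noev],
    kind = "hba1c",
    value = round(runif(length(noev), 40, 47.4), 1)
  )
  oth <- which(label == "other_diabetes")
  clin_oth <- tibble::tibble(
    patient_id = ids[oth],
    date = pmin(dx_date[oth] + sample(0:60, length(oth), replace = TRUE), STUDY_END),
    kind = "other_diabetes_code", value = NA_real_
  )
  pcos <- which(label == "pcos")
  clin_pcos <- tibble::tibble(
    patient_id = ids[pcos],
    date = dx_date[pcos] - sample(0:1000, length(pcos), replace = TRUE),
    kind = "pcos_code", value = NA_real_
  )
  clinical <- dplyr::arrange(
    dplyr::bind_rows(clin_dx, clin_hb, clin_pre, clin_noev, clin_oth, clin_pcos),
    .data$patient_id, .data$date, .data$kind
  )

  demographics <- tibble::tibble(patient_id = ids, birth_year = birth_year)

  reason_of <- c(
    clean = "ok", early_onset = "age_at_dx_lt_35",
    early_insulin = "insulin_within_12m", other_diabetes = "other_diabetes_code",
    pcos = "pcos_code", no_evidence = "no_diabetes_evidence"
  )
  inclusion <- tibble::tibble(
    patient_id = ids,
    included = label == "clean",
    reason = unname(reason_of[label]),
    diagnosis_date = dplyr::if_else(label == "clean", dx_date, as.Date(NA)),
    era = era_name
  )

  list(
    prescriptions = prescriptions,
    clinical = clinical,
    demographics = demographics,
    truth = list(
      line_mix = line_mix_truth(config),
      inclusion = inclusion,
      lines = lines_truth
    ),
    config = config
  )
}

# -- practice-level generator ------------------------------------------------

# chemical composition within each class for aggregated datasets; the
# DPP-4 entry includes a metformin combination product, which the
# aggregated convention counts as DPP-4 only
CLASS_CHEMICAL_SPLIT <- list(
  metformin = c("Metformin Hydrochloride" = 1),
  sulphonylurea = c("Gliclazide" = 0.7, "Glimepiride" = 0.3),
  TZD = c("Pioglitazone" = 0.9, "Rosiglitazone Maleate" = 0.1),
  DPP4 = c("Sitagliptin" = 0.55, "Linagliptin" = 0.25,
           "Metformin Hydrochloride/Sitagliptin" = 0.2),
  GLP1 = c("Liraglutide" = 0.6, "Exenatide" = 0.4),
  SGLT2 = c("Dapagliflozin" = 0.5, "Empagliflozin" = 0.3, "Canagliflozin" = 0.2),
  other = c("Acarbose" = 0.6, "Repaglinide" = 0.4)
)

# synthetic BNF paragraph 6.1.2 codes per chemical
bnf_code_of <- function(chemical) {
  all_chems <- unique(unlist(lapply(CLASS_CHEMICAL_SPLIT, names)))
  codes <- setNames(sprintf("060102%02d0", seq_along(all_chems)), all_chems)
  out <- codes[chemical]
  out[is.na(out)] <- "060102990"
  unname(out)
}

#' Practice-level simulation configuration
#'
#' Defaults describe a small synthetic prescribing landscape: CCG-level
#' class mixes drawn around a national mix (metformin ~55.6%,
#' sulphonylureas ~21.6%, DPP-4 ~13.5%, TZD ~2.5%, SGLT-2 ~4.1%, GLP-1
#' ~2.4%) with Dirichlet dispersion, per-practice mixes dispersed around
#' their CCG mean, unit costs reflecting cheap generics versus ~£40/item
#' gliptins and flozins, and planted closed/dormant/non-GP practices for
#' the filtering rules to remove.
#'
#' @param n_ccgs number of CCGs.
#' @param practices_per_ccg practices per CCG.
#' @param seed integer RNG seed.
#' @param months Date vector of month starts (default the 12 months to
#'   August 2017).
#' @param list_size_meanlog,list_size_sdlog log-normal parameters of the
#'   practice population aged >= 15.
#' @param prevalence_mean,prevalence_sd QOF all-type diabetes prevalence
#'   distribution (%), truncated to (3, 12).
#' @param national_shares national class mix the CCG means are drawn
#'   around (proportions summing to 1, in thousandths).
#' @param ccg_concentration Dirichlet concentration of CCG means around
#'   the national mix (`Inf` = all CCGs identical).
#' @param practice_concentration Dirichlet concentration of practice mixes
#'   around their CCG mean.
#' @param zero_dispersion if `TRUE`, every practice-month reproduces its
#'   CCG mix exactly (1000 items split in planted thousandths) — a
#'   diagnostic configuration for exact-recovery tests.
#' @param items_per_patient_year expected antidiabetic items per patient
#'   with diabetes per year.
#' @param unit_costs GBP per item by class.
#' @param prop_closed,prop_dormant,prop_non_gp planted fractions of
#'   closed, dormant and non-GP-setting practices.
#' @return a `geo_sim_config` list.
#' @export
geo_sim_config <- function(n_ccgs = 10, practices_per_ccg = 10, seed = 1L,
                           months = month_seq("2017-08", 12),
                           list_size_meanlog = log(7000), list_size_sdlog = 0.35,
                           prevalence_mean = 6.5, prevalence_sd = 0.7,
                           national_shares = c(
                             metformin = 0.556, sulphonylurea = 0.216,
                             TZD = 0.025, DPP4 = 0.135, GLP1 = 0.024,
                             SGLT2 = 0.041, other = 0.003
                           ),
                           ccg_concentration = 150,
                           practice_concentration = 150,
                           zero_dispersion = FALSE,
                           items_per_patient_year = 11.6,
                           unit_costs = c(
                             metformin = 4, sulphonylurea = 5, TZD = 12,
                             DPP4 = 40, GLP1 = 80, SGLT2 = 40, other = 10
                           ),
                           prop_closed = 0.05, prop_dormant = 0.03,
                           prop_non_gp = 0.05) {
  stopifnot(setequal(names(national_shares), ALL_CLASSES))
  national_shares <- national_shares[ALL_CLASSES]
  if (any(national_shares < 0) || abs(sum(national_shares) - 1) > 1e-8) {
    stop("national_shares must be non-negative and sum to 1")
  }
  stopifnot(setequal(names(unit_costs), ALL_CLASSES))
  unit_costs <- unit_costs[ALL_CLASSES]
  if (any(unit_costs <= 0)) stop("unit costs must be positive")
  if (prop_closed + prop_dormant >= 1 || prop_non_gp >= 1) {
    stop("planted practice contamination fractions are too large")
  }
  structure(as.list(environment()), class = "geo_sim_config")
}

#' Simulate a practice-level dispensing dataset with known ground truth
#'
#' Generates practice-month prescribing rows (one per chemical), practice
#' metadata (CCG membership, setting code, status, list size, QOF
#' prevalence), and the planted truth: per-CCG class shares, estimated
#' patient denominators, and realised items/cost per patient computed from
#' the generated rows restricted to eligible (active, setting-4)
#' practices. Under `zero_dispersion` every practice-month reproduces its
#' CCG mix exactly, so the realised CCG shares equal the planted shares.
#'
#' @param config a [geo_sim_config()].
#' @return list with `rows`, `meta`, `truth` (list of `ccg`,
#'   `ccg_shares_planted`, `practice_status`) and `config`.
#' @export
simulate_geo <- function(config = geo_sim_config()) {
  stopifnot(inherits(config, "geo_sim_config"))
  set.seed(config$seed)
  n_pr <- config$n_ccgs * config$practices_per_ccg
  practice_id <- sprintf("PR%04d", seq_len(n_pr))
  ccg_id <- sprintf("CCG%03d", rep(seq_len(config$n_ccgs),
                                   each = config$practices_per_ccg))

  status <- sample(c("active", "closed", "dormant"), n_pr, replace = TRUE,
                   prob = c(1 - config$prop_closed - config$prop_dormant,
                            config$prop_closed, config$prop_dormant))
  setting_code <- ifelse(runif(n_pr) < config$prop_non_gp,
                         sample(c(1L, 9L), n_pr, replace = TRUE), 4L)
  meta <- tibble::tibble(
    practice_id = practice_id, ccg_id = ccg_id,
    setting_code = as.integer(setting_code), status = status,
    list_size_15plus = pmax(1000, round(rlnorm(n_pr, config$list_size_meanlog,
                                               config$list_size_sdlog))),
    qof_prevalence = round(pmin(pmax(rnorm(n_pr, config$prevalence_mean,
                                           config$prevalence_sd), 3), 12), 2)
  )

  # planted CCG class mixes, in exact thousandths
  ccg_mix <- if (is.infinite(config$ccg_concentration)) {
    matrix(rep(config$national_shares, config$n_ccgs), nrow = config$n_ccgs,
           byrow = TRUE, dimnames = list(NULL, ALL_CLASSES))
  } else {
    rdirichlet(config$n_ccgs, config$national_shares * config$ccg_concentration)
  }
  ccg_mix <- t(apply(ccg_mix, 1, round_to_thousandths))
  colnames(ccg_mix) <- ALL_CLASSES
  rownames(ccg_mix) <- sprintf("CCG%03d", seq_len(config$n_ccgs))

  practice_mix <- if (config$zero_dispersion ||
                      is.infinite(config$practice_concentration)) {
    ccg_mix[ccg_id, , drop = FALSE]
  } else {
    t(vapply(seq_len(n_pr), function(i) {
      alpha <- pmax(ccg_mix[ccg_id[i], ], 1e-6) * config$practice_concentration
      rdirichlet(1, alpha)[1, ]
    }, numeric(length(ALL_CLASSES))))
  }
  colnames(practice_mix) <- ALL_CLASSES

  n_months <- length(config$months)
  # per practice-month totals
  totals <- if (config$zero_dispersion) {
    rep(1000L, n_pr)
  } else {
    target <- meta$list_size_15plus * meta$qof_prevalence / 100 *
      config$items_per_patient_year / 12
    pmax(1L, round(target))
  }

  # items per (practice, month, class): one multinomial draw per
  # practice-month (or the exact thousandth split under zero dispersion)
  n_classes <- length(ALL_CLASSES)
  counts <- matrix(0L, n_pr * n_months, n_classes,
                   dimnames = list(NULL, ALL_CLASSES))
  if (config$zero_dispersion) {
    counts[] <- as.integer(practice_mix[rep(seq_len(n_pr), each = n_months), ] * 1000)
  } else {
    for (i in seq_len(n_pr)) {
      draws <- rmultinom(n_months, totals[i], practice_mix[i, ])
      counts[(i - 1) * n_months + seq_len(n_months), ] <- t(draws)
    }
  }
  by_class <- tibble::tibble(
    practice_id = rep(practice_id, each = n_months),
    month = rep(config$months, times = n_pr)
  )

  # split class items across chemicals (largest remainder keeps totals)
  split_rows <- lapply(ALL_CLASSES, function(cl) {
    w <- CLASS_CHEMICAL_SPLIT[[cl]]
    alloc <- row_largest_remainder(counts[, cl], w)
    long <- tibble::tibble(
      practice_id = rep(by_class$practice_id, times = length(w)),
      month = rep(by_class$month, times = length(w)),
      chemical = rep(names(w), each = nrow(by_class)),
      items = as.integer(alloc),
      actual_cost = round(as.integer(alloc) * config$unit_costs[[cl]], 2)
    )
    long[long$items > 0, , drop = FALSE]
  })
  rows <- dplyr::bind_rows(split_rows)
  rows$bnf_code <- bnf_code_of(rows$chemical)
  rows <- dplyr::arrange(
    rows[, c("practice_id", "month", "bnf_code", "chemical", "items", "actual_cost")],
    .data$practice_id, .data$month, .data$chemical
  )

  # realised truth over eligible practices (active, setting 4)
  eligible <- meta$practice_id[meta$status == "active" & meta$setting_code == 4L]
  cls_of_chem <- setNames(
    rep(names(CLASS_CHEMICAL_SPLIT), lengths(CLASS_CHEMICAL_SPLIT)),
    unlist(lapply(CLASS_CHEMICAL_SPLIT, names))
  )
  el <- rows[rows$practice_id %in% eligible, ]
  el$class <- unname(cls_of_chem[el$chemical])
  el$ccg_id <- setNames(ccg_id, practice_id)[el$practice_id]
  realised <- dplyr::summarise(
    dplyr::group_by(el, .data$ccg_id,
                    class = factor(.data$class, levels = ALL_CLASSES), .drop = FALSE),
    items = sum(.data$items), .groups = "drop"
  )
  realised <- dplyr::mutate(
    dplyr::group_by(realised, .data$ccg_id),
    share_percent = .data$items / sum(.data$items) * 100
  )
  realised_wide <- tidyr::pivot_wider(
    dplyr::select(dplyr::ungroup(realised), "ccg_id", "class", "share_percent"),
    names_from = "class", values_from = "share_percent", names_prefix = "share_"
  )
  ccg_totals <- dplyr::summarise(
    dplyr::group_by(el, .data$ccg_id),
    items_total = sum(.data$items), cost_total = sum(.data$actual_cost),
    .groups = "drop"
  )
  denom <- diabetes_denominator(meta)
  truth_ccg <- dplyr::left_join(ccg_totals, realised_wide, by = "ccg_id")
  truth_ccg <- dplyr::left_join(
    truth_ccg, dplyr::select(denom, "ccg_id", "n_patients"), by = "ccg_id"
  )
  truth_ccg$items_per_patient <- truth_ccg$items_total / truth_ccg$n_patients
  truth_ccg$cost_per_patient <- truth_ccg$cost_total / truth_ccg$n_patients

  planted <- tibble::as_tibble(ccg_mix * 100)
  planted$ccg_id <- rownames(ccg_mix)
  planted <- dplyr::select(planted, "ccg_id", dplyr::everything())

  list(
    rows = rows,
    meta = meta,
    truth = list(
      ccg = dplyr::arrange(truth_ccg, .data$ccg_id),
      ccg_shares_planted = planted,
      practice_status = dplyr::count(meta, .data$status, .data$setting_code)
    ),
    config = config
  )
}

# -- national (annual dispensing) generator ----------------------------------

#' Default planted national per-patient trajectory
#'
#' A planted per-class trajectory of items and inflation-corrected cost
#' per person with type 2 diabetes, 1998-2016, built by linear
#' interpolation between anchor years. Non-metformin totals run 4.1 to 4.8
#' items (2008 to 2016) and £66 to £102, so the worked percent-change
#' arithmetic can be recomputed end-to-end from the synthetic table.
#'
#' @return tibble `year`, `class`, `items_per_patient`,
#'   `cost_per_patient_real`.
#' @export
default_national_trajectory <- function() {
  years <- 1998:2016
  interp <- function(knot_years, knot_values) {
    stats::approx(knot_years, knot_values, xout = years)$y
  }
  nm_items <- interp(c(1998, 2008, 2016), c(3.2, 4.1, 4.8))
  nm_cost <- interp(c(1998, 2008, 2016), c(40, 66, 102))
  # within-non-metformin weights at anchor years (each column sums to 1)
  item_w <- list(
    sulphonylurea = c(0.72, 0.55, 0.30), TZD = c(0.02, 0.25, 0.05),
    DPP4 = c(0, 0.07, 0.40), GLP1 = c(0, 0.02, 0.08),
    SGLT2 = c(0, 0, 0.125), other = c(0.26, 0.11, 0.045)
  )
  cost_w <- list(
    sulphonylurea = c(0.55, 0.25, 0.05), TZD = c(0.05, 0.45, 0.05),
    DPP4 = c(0, 0.18, 0.42), GLP1 = c(0, 0.09, 0.21),
    SGLT2 = c(0, 0, 0.24), other = c(0.40, 0.03, 0.03)
  )
  anchors <- c(1998, 2008, 2016)
  nm <- dplyr::bind_rows(lapply(names(item_w), function(cl) {
    tibble::tibble(
      year = years, class = cl,
      items_per_patient = nm_items * interp(anchors, item_w[[cl]]),
      cost_per_patient_real = nm_cost * interp(anchors, cost_w[[cl]])
    )
  }))
  met <- tibble::tibble(
    year = years, class = "metformin",
    items_per_patient = interp(anchors, c(1.5, 4.5, 6.5)),
    cost_per_patient_real = interp(anchors, c(8, 18, 24))
  )
  dplyr::arrange(dplyr::bind_rows(met, nm), .data$year, .data$class)
}

#' Construct a synthetic annual dispensing table from a planted trajectory
#'
#' Inverts the per-patient normalisation: given planted items and
#' inflation-corrected cost per patient, a prevalence series, mid-year
#' populations and a CPI table, produces an annual dispensing table (one
#' row per year and chemical, with item counts and nominal net ingredient
#' cost) from which the trend pipeline recovers the planted trajectory up
#' to integer/penny rounding.
#'
#' @param trajectory tibble as from [default_national_trajectory()].
#' @param prevalence tibble `year`, `prevalence` (%) covering the
#'   trajectory years.
#' @param population tibble `year`, `population`.
#' @param cpi tibble `year`, `index`.
#' @param base_year CPI base year (default 2016).
#' @return tibble `year`, `chemical`, `items`, `nic`.
#' @export
synthetic_pca_table <- function(trajectory, prevalence, population, cpi,
                                base_year = 2016) {
  stopifnot(all(c("year", "class", "items_per_patient", "cost_per_patient_real")
                %in% names(trajectory)))
  prev <- setNames(prevalence$prevalence, as.character(prevalence$year))
  pop <- setNames(population$population, as.character(population$year))
  miss <- setdiff(unique(trajectory$year),
                  intersect(prevalence$year, population$year))
  if (length(miss) > 0) {
    stop("denominator table missing year(s): ", paste(miss, collapse = ", "))
  }
  patients <- prev[as.character(trajectory$year)] * 10 *
    pop[as.character(trajectory$year)] / 1000
  items_class <- trajectory$items_per_patient * patients
  cost_real_class <- trajectory$cost_per_patient_real * patients
  # deflate back to nominal prices
  idx <- setNames(cpi$index, as.character(cpi$year))
  nic_class <- cost_real_class * unname(idx[as.character(trajectory$year)]) /
    unname(idx[as.character(base_year)])
  out <- lapply(seq_len(nrow(trajectory)), function(r) {
    w <- CLASS_CHEMICAL_SPLIT[[trajectory$class[r]]]
    items <- largest_remainder(w, round(items_class[r]))
    keep <- items > 0
    if (!any(keep)) return(NULL)
    tibble::tibble(
      year = trajectory$year[r], chemical = names(w)[keep], items = items[keep],
      nic = round(nic_class[r] * items[keep] / sum(items), 2)
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$year, .data$chemical)
}
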