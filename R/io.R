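# Readers and writers for the CSV dialects the pipeline consumes and
# produces. Readers validate column presence (erroring with the column
# name), collect malformed rows into a rejects report rather than dropping
# them silently, and return typed tibbles.

read_raw_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) stop("no data rows in ", basename(path))
  raw
}

# attach a rejects tibble and warn about it
with_rejects <- function(out, raw, bad, path) {
  if (any(bad)) {
    rejects <- raw[bad, , drop = FALSE]
    rejects$row <- which(bad) + 1L # file line (header is line 1)
    attr(out, "rejects") <- rejects
    warning(sum(bad), " malformed row(s) rejected from ", basename(path),
            call. = FALSE)
  } else {
    attr(out, "rejects") <- raw[0, , drop = FALSE]
  }
  out
}

is_iso_date <- function(x) !is.na(as.Date(x, format = "%Y-%m-%d"))
is_count <- function(x) {
  suppressWarnings(v <- as.numeric(x))
  !is.na(v) & v >= 0 & v == floor(v)
}
is_nonneg <- function(x) {
  suppressWarnings(v <- as.numeric(x))
  !is.na(v) & v >= 0
}

#' Read a practice-level prescribing CSV (NHS-dialect)
#'
#' Columns `PRACTICE,BNF CODE,BNF NAME,ITEMS,ACT COST,PERIOD` (period
#' `YYYYMM`). Malformed rows (bad counts, costs or periods) are collected
#' into a rejects report attached as attribute `"rejects"` and reported
#' with a warning, not silently dropped. A missing mandatory column or an
#' empty file is an error.
#'
#' @param path file path.
#' @return tidy tibble `practice_id`, `month` (Date, first of month),
#'   `bnf_code`, `chemical`, `items`, `actual_cost`, with attribute
#'   `rejects`.
#' @export
read_prescribing_csv <- function(path) {
  required <- c("PRACTICE", "BNF CODE", "BNF NAME", "ITEMS", "ACT COST", "PERIOD")
  raw <- read_raw_csv(path, required)
  ok_period <- grepl("^[0-9]{6}$", raw$PERIOD) &
    suppressWarnings(as.integer(substr(raw$PERIOD, 5, 6))) %in% 1:12
  bad <- is.na(raw$PRACTICE) | is.na(raw$`BNF NAME`) |
    !is_count(raw$ITEMS) | !is_nonneg(raw$`ACT COST`) | !ok_period
  keep <- raw[!bad, , drop = FALSE]
  out <- tibble::tibble(
    practice_id = keep$PRACTICE,
    month = as.Date(paste0(substr(keep$PERIOD, 1, 4), "-",
                           substr(keep$PERIOD, 5, 6), "-01")),
    bnf_code = keep$`BNF CODE`,
    chemical = keep$`BNF NAME`,
    items = as.integer(keep$ITEMS),
    actual_cost = as.numeric(keep$`ACT COST`)
  )
  with_rejects(out, raw, bad, path)
}

#' Write a practice-level prescribing CSV (NHS-dialect)
#'
#' Inverse of [read_prescribing_csv()].
#'
#' @param rows tidy practice rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prescribing_csv <- function(rows, path) {
  check_practice_rows(rows)
  out <- tibble::tibble(
    PRACTICE = rows$practice_id,
    `BNF CODE` = if ("bnf_code" %in% names(rows)) rows$bnf_code else "060102000",
    `BNF NAME` = rows$chemical,
    ITEMS = rows$items,
    `ACT COST` = rows$actual_cost,
    PERIOD = format(rows$month, "%Y%m")
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read patient-level prescription events
#'
#' Columns `patient_id,date,drug_name,constituents,is_insulin` (dates
#' ISO-8601; `constituents` semicolon-separated). Malformed rows are
#' rejected with a warning (attribute `rejects`).
#'
#' @param path file path.
#' @return tibble of prescription events.
#' @export
read_prescriptions_csv <- function(path) {
  required <- c("patient_id", "date", "drug_name", "constituents", "is_insulin")
  raw <- read_raw_csv(path, required)
  bad <- is.na(raw$patient_id) | !is_iso_date(raw$date) | is.na(raw$drug_name) |
    !tolower(raw$is_insulin) %in% c("true", "false")
  keep <- raw[!bad, , drop = FALSE]
  out <- tibble::tibble(
    patient_id = keep$patient_id,
    date = as.Date(keep$date),
    drug_name = keep$drug_name,
    constituents = keep$constituents,
    is_insulin = tolower(keep$is_insulin) == "true"
  )
  with_rejects(out, raw, bad, path)
}

#' Read patient-level clinical events
#'
#' Columns `patient_id,date,kind,value` with `kind` one of
#' `diabetes_dx_code`, `other_diabetes_code`, `pcos_code`, `hba1c`;
#' `value` is the HbA1c result (mmol/mol) and must be present and positive
#' iff `kind == "hba1c"`.
#'
#' @param path file path.
#' @return tibble of clinical events.
#' @export
read_clinical_csv <- function(path) {
  required <- c("patient_id", "date", "kind", "value")
  raw <- read_raw_csv(path, required)
  kinds <- c("diabetes_dx_code", "other_diabetes_code", "pcos_code", "hba1c")
  suppressWarnings(val <- as.numeric(raw$value))
  bad <- is.na(raw$patient_id) | !is_iso_date(raw$date) | !raw$kind %in% kinds |
    (raw$kind == "hba1c" & (is.na(val) | val <= 0)) |
    (raw$kind != "hba1c" & !is.na(val))
  keep <- raw[!bad, , drop = FALSE]
  out <- tibble::tibble(
    patient_id = keep$patient_id,
    date = as.Date(keep$date),
    kind = keep$kind,
    value = suppressWarnings(as.numeric(keep$value))
  )
  with_rejects(out, raw, bad, path)
}

#' Read the patient demographics roster
#'
#' Columns `patient_id,birth_year`; one row per patient.
#'
#' @param path file path.
#' @return tibble `patient_id`, `birth_year`.
#' @export
read_demographics_csv <- function(path) {
  raw <- read_raw_csv(path, c("patient_id", "birth_year"))
  bad <- is.na(raw$patient_id) | !is_count(raw$birth_year)
  keep <- raw[!bad, , drop = FALSE]
  out <- tibble::tibble(
    patient_id = keep$patient_id,
    birth_year = as.integer(keep$birth_year)
  )
  with_rejects(out, raw, bad, path)
}

#' Read practice metadata
#'
#' Columns `practice_id,ccg_id,setting_code,status,list_size_15plus,
#' qof_prevalence`.
#'
#' @param path file path.
#' @return tibble of practice metadata.
#' @export
read_practice_meta_csv <- function(path) {
  required <- c("practice_id", "ccg_id", "setting_code", "status",
                "list_size_15plus", "qof_prevalence")
  raw <- read_raw_csv(path, required)
  out <- tibble::tibble(
    practice_id = raw$practice_id,
    ccg_id = raw$ccg_id,
    setting_code = as.integer(raw$setting_code),
    status = raw$status,
    list_size_15plus = as.integer(raw$list_size_15plus),
    qof_prevalence = as.numeric(raw$qof_prevalence)
  )
  check_practice_meta(out)
}

#' Read an annual dispensing (PCA-like) table
#'
#' Columns `year,chemical,items,nic`.
#'
#' @param path file path.
#' @return tibble `year`, `chemical`, `items`, `nic`.
#' @export
read_pca_csv <- function(path) {
  raw <- read_raw_csv(path, c("year", "chemical", "items", "nic"))
  bad <- !is_count(raw$year) | is.na(raw$chemical) | !is_count(raw$items) |
    !is_nonneg(raw$nic)
  keep <- raw[!bad, , drop = FALSE]
  out <- tibble::tibble(
    year = as.integer(keep$year), chemical = keep$chemical,
    items = as.numeric(keep$items), nic = as.numeric(keep$nic)
  )
  with_rejects(out, raw, bad, path)
}

#' Read a consumer price index table
#' @param path file path (columns `year,index`).
#' @return tibble `year`, `index`.
#' @export
read_cpi_csv <- function(path) {
  raw <- read_raw_csv(path, c("year", "index"))
  tibble::tibble(year = as.integer(raw$year), index = as.numeric(raw$index))
}

#' Read a mid-year population table
#' @param path file path (columns `year,population`).
#' @return tibble `year`, `population`.
#' @export
read_population_csv <- function(path) {
  raw <- read_raw_csv(path, c("year", "population"))
  tibble::tibble(year = as.integer(raw$year), population = as.numeric(raw$population))
}

#' Read an observed prevalence table
#' @param path file path (columns `year,prevalence`, percent).
#' @return tibble `year`, `prevalence`.
#' @export
read_prevalence_csv <- function(path) {
  raw <- read_raw_csv(path, c("year", "prevalence"))
  tibble::tibble(year = as.integer(raw$year), prevalence = as.numeric(raw$prevalence))
}
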