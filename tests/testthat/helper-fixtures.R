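# Shared fixtures: the shipped class map and small constructors for the
# event tables the cohort/lines modules consume.

CM <- read_class_map()

rx_tbl <- function(patient_id, date, drug_name, is_insulin = FALSE,
                   constituents = NA_character_) {
  tibble::tibble(
    patient_id = patient_id,
    date = as.Date(date),
    drug_name = drug_name,
    constituents = constituents,
    is_insulin = is_insulin
  )
}

clin_tbl <- function(patient_id = character(), date = character(),
                     kind = character(), value = NA_real_) {
  tibble::tibble(
    patient_id = patient_id,
    date = as.Date(date),
    kind = kind,
    value = value
  )
}

demo_tbl <- function(patient_id, birth_year) {
  tibble::tibble(patient_id = patient_id, birth_year = birth_year)
}

empty_clinical <- function() clin_tbl()
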