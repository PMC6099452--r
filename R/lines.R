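# Therapy-line construction: first-ever class starts, gap-based treatment
# episodes, line assignment 1-4, and annual per-line class share tables.
#
# A "new start" is the first-ever prescription of a drug in each class for
# each patient, even if only prescribed once; every new start is assigned to
# the next line of therapy regardless of concomitant treatment. Restarts
# after a stop-gap do not create new line events; episodes are computed and
# exposed separately for inspection.

DEFAULT_GAP_DAYS <- 183 # "at least 6 months" between issues closes an episode

# classify patient-level prescriptions into (patient_id, class, date) rows,
# combination products contributing both constituent classes
exploded_class_rows <- function(prescriptions, class_map) {
  check_prescriptions(prescriptions)
  rx <- dplyr::filter(prescriptions, !.data$is_insulin)
  if (nrow(rx) == 0) {
    return(tibble::tibble(patient_id = character(), class = character(),
                          date = as.Date(character())))
  }
  names_in <- if ("constituents" %in% names(rx) &&
                  !all(is.na(rx$constituents) | rx$constituents == "")) {
    dplyr::coalesce(dplyr::na_if(rx$constituents, ""), rx$drug_name)
  } else {
    rx$drug_name
  }
  cls <- classify_items(names_in, mode = "patient_level", class_map = class_map)
  tibble::tibble(
    patient_id = rx$patient_id[cls$item],
    class = cls$class,
    date = rx$date[cls$item]
  )
}

#' Detect first-ever class starts
#'
#' One entry per (patient, class) ever prescribed, at its earliest date.
#' Combination products contribute both constituent classes at the
#' combination's date (patient-level convention). Input order is
#' irrelevant.
#'
#' @inheritParams diagnosis_dates
#' @param class_map a `drug_class_map` (see [read_class_map()]).
#' @return tibble `patient_id`, `class`, `date`, sorted by patient and
#'   date.
#' @export
detect_new_starts <- function(prescriptions, class_map) {
  rows <- exploded_class_rows(prescriptions, class_map)
  out <- dplyr::summarise(
    dplyr::group_by(rows, .data$patient_id, .data$class),
    date = min_date(.data$date), .groups = "drop"
  )
  dplyr::arrange(out, .data$patient_id, .data$date, .data$class)
}

#' Build gap-based treatment episodes
#'
#' Within each (patient, class), consecutive prescription dates closer than
#' `gap_days` share an episode; a gap of at least `gap_days` closes the
#' episode at the last prescription date and opens a new one. Duplicate
#' same-day prescriptions do not affect segmentation. The final episode of
#' each (patient, class) is flagged `open`.
#'
#' @inheritParams detect_new_starts
#' @param gap_days stop-gap threshold in days; default 183 ("6 months").
#' @return tibble `patient_id`, `class`, `episode`, `start_date`,
#'   `end_date`, `open`.
#' @export
build_episodes <- function(prescriptions, class_map, gap_days = DEFAULT_GAP_DAYS) {
  stopifnot(is.numeric(gap_days), gap_days > 0)
  rows <- dplyr::distinct(exploded_class_rows(prescriptions, class_map))
  rows <- dplyr::arrange(rows, .data$patient_id, .data$class, .data$date)
  rows <- dplyr::group_by(rows, .data$patient_id, .data$class)
  rows <- dplyr::mutate(
    rows,
    gap = as.numeric(.data$date - dplyr::lag(.data$date)),
    episode = cumsum(is.na(.data$gap) | .data$gap >= gap_days)
  )
  eps <- dplyr::summarise(
    dplyr::group_by(rows, .data$patient_id, .data$class, .data$episode),
    start_date = min_date(.data$date),
    end_date = max_date(.data$date),
    .groups = "drop_last"
  )
  eps <- dplyr::mutate(eps, open = .data$episode == max(.data$episode))
  dplyr::arrange(dplyr::ungroup(eps), .data$patient_id, .data$class, .data$episode)
}

#' Assign therapy lines 1-4 to class starts
#'
#' Starts are ordered by date (same-date ties broken metformin-first, then
#' alphabetically by class) and numbered 1-4; starts beyond the fourth are
#' dropped, as are starts on or after the patient's first insulin
#' prescription (insulin censors further line assignment).
#'
#' @param new_starts tibble from [detect_new_starts()].
#' @param insulin_dates optional tibble `patient_id`, `insulin_date` (first
#'   insulin prescription per patient).
#' @param max_line highest line retained (default 4).
#' @return tibble `patient_id`, `class`, `line`, `start_date`,
#'   `calendar_year`.
#' @export
assign_lines <- function(new_starts, insulin_dates = NULL, max_line = 4L) {
  stopifnot(all(c("patient_id", "class", "date") %in% names(new_starts)))
  starts <- new_starts
  if (!is.null(insulin_dates) && nrow(insulin_dates) > 0) {
    stopifnot(all(c("patient_id", "insulin_date") %in% names(insulin_dates)))
    starts <- dplyr::left_join(starts, insulin_dates, by = "patient_id")
    starts <- dplyr::filter(
      starts, is.na(.data$insulin_date) | .data$date < .data$insulin_date
    )
    starts$insulin_date <- NULL
  }
  starts <- dplyr::arrange(
    starts, .data$patient_id, .data$date, .data$class != "metformin", .data$class
  )
  starts <- dplyr::mutate(
    dplyr::group_by(starts, .data$patient_id), line = dplyr::row_number()
  )
  starts <- dplyr::filter(dplyr::ungroup(starts), .data$line <= max_line)
  tibble::tibble(
    patient_id = starts$patient_id,
    class = starts$class,
    line = as.integer(starts$line),
    start_date = starts$date,
    calendar_year = as.integer(format(starts$date, "%Y"))
  )
}

#' Annual class shares per therapy line
#'
#' For each (calendar year, line) with at least one event, the percentage
#' of new prescriptions by class: class count divided by the cell total,
#' times 100. Empty cells are absent rather than zero.
#'
#' @param line_events tibble from [assign_lines()].
#' @return tibble `calendar_year`, `line`, `class`, `n`, `percent`;
#'   percentages sum to 100 within each (year, line).
#' @export
line_share_table <- function(line_events) {
  stopifnot(all(c("calendar_year", "line", "class") %in% names(line_events)))
  if (nrow(line_events) == 0) stop("no line events supplied")
  counts <- dplyr::count(
    line_events, .data$calendar_year, .data$line, .data$class, name = "n"
  )
  counts <- dplyr::mutate(
    dplyr::group_by(counts, .data$calendar_year, .data$line),
    percent = .data$n / sum(.data$n) * 100
  )
  dplyr::arrange(
    dplyr::ungroup(counts), .data$calendar_year, .data$line, .data$class
  )
}
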