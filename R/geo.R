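# Geographic variation: practice filtering, CCG aggregation over a
# 12-month window, distribution summaries, decile time series and the
# lowest-decile potential-savings estimator.

PRACTICE_SETTING_GP <- 4L

check_practice_rows <- function(rows) {
  need <- c("practice_id", "month", "chemical", "items", "actual_cost")
  missing <- setdiff(need, names(rows))
  if (length(missing) > 0) {
    stop("practice rows are missing column(s): ", paste(missing, collapse = ", "))
  }
  stopifnot(inherits(rows$month, "Date"))
  if (any(rows$items < 0) || any(rows$actual_cost < 0)) {
    stop("items and actual_cost must be non-negative")
  }
  invisible(rows)
}

check_practice_meta <- function(meta) {
  need <- c("practice_id", "ccg_id", "setting_code", "status",
            "list_size_15plus", "qof_prevalence")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0) {
    stop("practice metadata is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(meta$practice_id)) stop("duplicated practice_id in metadata")
  bad <- setdiff(unique(meta$status), c("active", "closed", "dormant"))
  if (length(bad) > 0) stop("unknown practice status value(s): ", paste(bad, collapse = ", "))
  if (any(meta$list_size_15plus < 0)) stop("list sizes must be non-negative")
  if (any(meta$qof_prevalence < 0 | meta$qof_prevalence >= 100)) {
    stop("qof_prevalence must be in [0, 100)")
  }
  invisible(meta)
}

# metadata restricted to standard, currently active general practices
eligible_meta <- function(meta) {
  dplyr::filter(meta, .data$setting_code == PRACTICE_SETTING_GP,
                .data$status == "active")
}

#' Filter practice-level rows to standard active general practices
#'
#' Keeps rows belonging to practices with setting code 4 (standard GP
#' practice) and current status "active"; prescribing from closed or
#' dormant practices and from other organisation types (prisons,
#' out-of-hours services, ...) is removed. The counts removed per reason
#' are attached as attribute `"removed"` and reported via `message()`.
#'
#' @param rows tibble of practice-month prescribing rows (`practice_id`,
#'   `month` (Date, first of month), `chemical`, `items`, `actual_cost`).
#' @param meta practice metadata tibble (`practice_id`, `ccg_id`,
#'   `setting_code`, `status`, `list_size_15plus`, `qof_prevalence`).
#' @param quiet suppress the message (default `FALSE`).
#' @return filtered rows, with attribute `removed` (tibble of `reason`,
#'   `n_practices`, `n_rows`).
#' @export
filter_practices <- function(rows, meta, quiet = FALSE) {
  check_practice_rows(rows)
  check_practice_meta(meta)
  status <- setNames(meta$status, meta$practice_id)
  setting <- setNames(meta$setting_code, meta$practice_id)
  st <- unname(status[rows$practice_id])
  se <- unname(setting[rows$practice_id])
  reason <- dplyr::case_when(
    is.na(st) ~ "unknown_practice",
    se != PRACTICE_SETTING_GP ~ "non_gp_setting",
    st == "closed" ~ "closed",
    st == "dormant" ~ "dormant",
    TRUE ~ "kept"
  )
  removed <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(practice_id = rows$practice_id, reason = reason), .data$reason
    ),
    n_practices = dplyr::n_distinct(.data$practice_id),
    n_rows = dplyr::n(), .groups = "drop"
  )
  removed <- dplyr::filter(removed, .data$reason != "kept")
  if (!quiet && nrow(removed) > 0) {
    message("filter_practices removed: ",
            paste(sprintf("%s (%d practices, %d rows)", removed$reason,
                          removed$n_practices, removed$n_rows), collapse = "; "))
  }
  out <- rows[reason == "kept", , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Estimated number of patients with diabetes per CCG
#'
#' Multiplies each CCG's registered population aged 15 and over (summed
#' practice list sizes) by its prevalence rate — the practice-list-size
#' weighted mean of QOF-recorded (all-type, adult) diabetes prevalence.
#' Only standard active GP practices contribute.
#'
#' @inheritParams filter_practices
#' @return tibble `ccg_id`, `list_size_15plus`, `prevalence_percent`,
#'   `n_patients`.
#' @export
diabetes_denominator <- function(meta) {
  check_practice_meta(meta)
  m <- eligible_meta(meta)
  out <- dplyr::summarise(
    dplyr::group_by(m, .data$ccg_id),
    prevalence_percent = sum(.data$list_size_15plus * .data$qof_prevalence) /
      sum(.data$list_size_15plus),
    list_size_15plus = sum(.data$list_size_15plus),
    .groups = "drop"
  )
  out <- out[, c("ccg_id", "list_size_15plus", "prevalence_percent")]
  if (any(out$list_size_15plus <= 0)) {
    stop("CCG(s) with zero registered population: ",
         paste(out$ccg_id[out$list_size_15plus <= 0], collapse = ", "))
  }
  out$n_patients <- out$list_size_15plus * out$prevalence_percent / 100
  dplyr::arrange(out, .data$ccg_id)
}

# latest n consecutive months present in the data
latest_window <- function(months, n = 12) {
  u <- sort(unique(months), decreasing = TRUE)
  if (length(u) < n) stop("data cover only ", length(u), " month(s); window needs ", n)
  sort(u[seq_len(n)])
}

#' Per-practice monthly class share table
#'
#' Classifies chemicals under the aggregated combination convention and
#' computes, for each practice and month, the percentage of items in each
#' class (all classes present, zero-filled). Practice-months with no
#' antidiabetic items are dropped.
#'
#' @inheritParams filter_practices
#' @param class_map a `drug_class_map`.
#' @return tibble `practice_id`, `month`, `class`, `items`,
#'   `share_percent`.
#' @export
practice_share_table <- function(rows, class_map) {
  check_practice_rows(rows)
  cls <- classify_items(rows$chemical, mode = "aggregated", class_map = class_map)
  classified <- tibble::tibble(
    practice_id = rows$practice_id[cls$item],
    month = rows$month[cls$item],
    class = factor(cls$class, levels = ALL_CLASSES),
    items = rows$items[cls$item] * cls$weight
  )
  agg <- dplyr::summarise(
    dplyr::group_by(classified, .data$practice_id, .data$month, .data$class,
                    .drop = FALSE),
    items = sum(.data$items), .groups = "drop"
  )
  # .drop = FALSE completes classes within observed (practice, month) pairs
  agg <- dplyr::mutate(
    dplyr::group_by(agg, .data$practice_id, .data$month),
    total = sum(.data$items)
  )
  agg <- dplyr::filter(dplyr::ungroup(agg), .data$total > 0)
  agg$share_percent <- agg$items / agg$total * 100
  agg$class <- as.character(agg$class)
  dplyr::arrange(
    dplyr::select(agg, -"total"),
    .data$practice_id, .data$month, .data$class
  )
}

#' CCG 12-month prescribing summary
#'
#' Aggregates (pre-filtered) practice rows over a window of consecutive
#' months to one row per CCG: class shares of summed items (aggregated
#' combination convention), plus items and actual cost per estimated
#' patient with diabetes. CCGs with no antidiabetic items in the window
#' are excluded with a warning.
#'
#' @inheritParams practice_share_table
#' @param meta practice metadata (supplies CCG membership and the
#'   prevalence denominator; see [diabetes_denominator()]).
#' @param window Date vector of months to aggregate; default the latest
#'   `window_months` months present in `rows`.
#' @param window_months window length when `window` is `NULL` (default
#'   12).
#' @return tibble with one row per CCG: `ccg_id`, `window_start`,
#'   `window_end`, `n_practices`, `n_patients`, `items_total`,
#'   `cost_total`, `items_per_patient`, `cost_per_patient`, one
#'   `share_<class>` column per class, and `share_non_met_non_su`.
#' @export
ccg_summary <- function(rows, meta, class_map, window = NULL, window_months = 12) {
  check_practice_rows(rows)
  check_practice_meta(meta)
  if (is.null(window)) window <- latest_window(rows$month, window_months)
  win <- dplyr::filter(rows, .data$month %in% window)
  if (nrow(win) == 0) stop("no rows fall inside the aggregation window")
  ccg_of <- setNames(meta$ccg_id, meta$practice_id)
  win$ccg_id <- unname(ccg_of[win$practice_id])
  if (anyNA(win$ccg_id)) {
    stop("practice(s) without metadata in window: ",
         paste(unique(win$practice_id[is.na(win$ccg_id)]), collapse = ", "))
  }
  cls <- classify_items(win$chemical, mode = "aggregated", class_map = class_map)
  classified <- tibble::tibble(
    ccg_id = win$ccg_id[cls$item],
    class = factor(cls$class, levels = ALL_CLASSES),
    items = win$items[cls$item] * cls$weight
  )
  by_class <- dplyr::summarise(
    dplyr::group_by(classified, .data$ccg_id, .data$class, .drop = FALSE),
    items = sum(.data$items), .groups = "drop"
  )
  totals <- dplyr::summarise(
    dplyr::group_by(win, .data$ccg_id),
    n_practices = dplyr::n_distinct(.data$practice_id),
    items_total = sum(.data$items),
    cost_total = sum(.data$actual_cost),
    .groups = "drop"
  )
  empty <- totals$ccg_id[totals$items_total <= 0]
  if (length(empty) > 0) {
    warning("CCG(s) with zero antidiabetic items excluded: ",
            paste(empty, collapse = ", "), call. = FALSE)
    totals <- dplyr::filter(totals, !.data$ccg_id %in% empty)
    by_class <- dplyr::filter(by_class, !.data$ccg_id %in% empty)
  }
  shares <- dplyr::mutate(
    dplyr::group_by(by_class, .data$ccg_id),
    share = .data$items / sum(.data$items) * 100
  )
  shares <- tidyr::pivot_wider(
    dplyr::select(dplyr::ungroup(shares), "ccg_id", "class", "share"),
    names_from = "class", values_from = "share", names_prefix = "share_"
  )
  denom <- diabetes_denominator(meta)
  out <- dplyr::inner_join(totals, shares, by = "ccg_id")
  out <- dplyr::left_join(out, dplyr::select(denom, "ccg_id", "n_patients"),
                          by = "ccg_id")
  if (anyNA(out$n_patients)) {
    stop("CCG(s) without an estimated patient denominator: ",
         paste(out$ccg_id[is.na(out$n_patients)], collapse = ", "))
  }
  out$items_per_patient <- out$items_total / out$n_patients
  out$cost_per_patient <- out$cost_total / out$n_patients
  out$share_non_met_non_su <- 100 - out$share_metformin - out$share_sulphonylurea
  out$window_start <- min(window)
  out$window_end <- max(window)
  cols <- c("ccg_id", "window_start", "window_end", "n_practices", "n_patients",
            "items_total", "cost_total", "items_per_patient", "cost_per_patient",
            paste0("share_", ALL_CLASSES), "share_non_met_non_su")
  dplyr::arrange(dplyr::select(out, dplyr::all_of(cols)), .data$ccg_id)
}

#' Distribution summary of a set of values
#'
#' Mean, sample standard deviation (n - 1), median, linear-interpolation
#' quartiles, interquartile range and excess kurtosis (moment formula
#' m4/m2^2 - 3; 0 for a normal distribution). Kurtosis is undefined (NA)
#' for constant input.
#'
#' @param x numeric vector (NAs dropped); at least 4 values.
#' @return one-row tibble `n`, `mean`, `sd`, `median`, `lower_quartile`,
#'   `upper_quartile`, `iqr`, `kurtosis`.
#' @export
distribution_stats <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 4) stop("need at least 4 values for quartiles and kurtosis")
  q <- quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  kurt <- if (var(x) == 0) NA_real_ else e1071::kurtosis(x, type = 1)
  tibble::tibble(
    n = length(x), mean = mean(x), sd = sd(x),
    median = q[2], lower_quartile = q[1], upper_quartile = q[3],
    iqr = q[3] - q[1], kurtosis = kurt
  )
}

#' Table-1-style distribution summary across CCGs
#'
#' Applies [distribution_stats()] to each variation measure of a CCG
#' summary table: the per-class shares, the combined
#' non-metformin/non-sulphonylurea share, and items and cost per patient.
#'
#' @param summaries tibble from [ccg_summary()].
#' @return tibble with one row per measure.
#' @export
ccg_distribution_table <- function(summaries) {
  measures <- c(paste0("share_", ALL_CLASSES), "share_non_met_non_su",
                "items_per_patient", "cost_per_patient")
  measures <- intersect(measures, names(summaries))
  rows <- lapply(measures, function(m) {
    cbind(tibble::tibble(measure = m), distribution_stats(summaries[[m]]))
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Decile time series of practice-level class shares
#'
#' For each month and class, the 10th to 90th percentiles
#' (linear-interpolation order statistics) of practice-level share.
#' Months with fewer practices than `min_practices` are skipped with a
#' warning. Percentile curves are non-decreasing within a month by
#' construction.
#'
#' @param shares tibble from [practice_share_table()].
#' @param min_practices minimum practices per month (default 10).
#' @return tibble `month`, `class`, `decile` (10, 20, ..., 90),
#'   `share_percent`.
#' @export
decile_series <- function(shares, min_practices = 10) {
  stopifnot(all(c("practice_id", "month", "class", "share_percent") %in% names(shares)))
  per_month <- dplyr::summarise(
    dplyr::group_by(shares, .data$month),
    n = dplyr::n_distinct(.data$practice_id), .groups = "drop"
  )
  thin <- per_month$month[per_month$n < min_practices]
  if (length(thin) > 0) {
    warning("month(s) skipped with fewer than ", min_practices, " practices: ",
            paste(format(thin, "%Y-%m"), collapse = ", "), call. = FALSE)
    shares <- dplyr::filter(shares, !.data$month %in% thin)
  }
  if (nrow(shares) == 0) stop("no months with enough practices")
  probs <- seq(0.1, 0.9, by = 0.1)
  out <- dplyr::reframe(
    dplyr::group_by(shares, .data$month, .data$class),
    decile = as.integer(probs * 100),
    share_percent = quantile(.data$share_percent, probs = probs, type = 7,
                             names = FALSE)
  )
  dplyr::arrange(out, .data$month, .data$class, .data$decile)
}

#' Potential savings at the lowest-decile cost per patient
#'
#' Benchmark = the unweighted 10th percentile of cost per patient across
#' CCGs (linear interpolation). Each CCG above the benchmark contributes
#' `(cost_per_patient - benchmark) * n_patients`; CCGs at or below it
#' contribute nothing (floored at zero).
#'
#' @param summaries tibble with `cost_per_patient` and `n_patients` (one
#'   row per CCG), e.g. from [ccg_summary()]; at least 10 CCGs.
#' @param probs benchmark percentile as a probability (default 0.1).
#' @return list with `total_spend`, `benchmark_cost_per_patient`,
#'   `total_saving` and `saving_fraction` (saving / total spend).
#' @export
savings_at_decile <- function(summaries, probs = 0.1) {
  stopifnot(all(c("cost_per_patient", "n_patients") %in% names(summaries)))
  if (nrow(summaries) < 10) stop("need at least 10 CCGs for a decile benchmark")
  cost <- summaries$cost_per_patient
  n <- summaries$n_patients
  b <- quantile(cost, probs = probs, type = 7, names = FALSE)
  saving <- sum(pmax(0, cost - b) * n)
  spend <- sum(cost * n)
  list(
    total_spend = spend,
    benchmark_cost_per_patient = b,
    total_saving = saving,
    saving_fraction = saving / spend
  )
}
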