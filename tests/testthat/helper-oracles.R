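# Independent oracles, deliberately written as plain loops / closed forms
# so they share no code with the implementation they check.

# brute-force first-occurrence sequencer: walks prescriptions in date
# order, opens each class the first time it appears, numbers lines 1..4
oracle_lines <- function(prescriptions, class_map, max_line = 4) {
  out <- list()
  for (pid in unique(prescriptions$patient_id)) {
    sub <- prescriptions[prescriptions$patient_id == pid & !prescriptions$is_insulin, ]
    firsts <- list()
    for (i in seq_len(nrow(sub))) {
      nm <- if (!is.na(sub$constituents[i]) && sub$constituents[i] != "") {
        sub$constituents[i]
      } else {
        sub$drug_name[i]
      }
      parts <- trimws(strsplit(nm, "[/;+]")[[1]])
      cls <- classify_chemical(parts, class_map)
      if (length(cls) == 2 && !anyNA(cls) && cls[1] != cls[2] &&
          !"metformin" %in% cls) {
        cls <- "other"
      }
      for (cl in unique(cls[!is.na(cls)])) {
        if (is.null(firsts[[cl]]) || sub$date[i] < firsts[[cl]]) {
          firsts[[cl]] <- sub$date[i]
        }
      }
    }
    if (length(firsts) == 0) next
    df <- data.frame(class = names(firsts),
                     date = as.Date(unlist(lapply(firsts, as.character))))
    df <- df[order(df$date, df$class != "metformin", df$class), ]
    df$line <- seq_len(nrow(df))
    df <- df[df$line <= max_line, ]
    df$patient_id <- pid
    out[[length(out) + 1]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$patient_id, res$line), c("patient_id", "class", "line", "date")]
}

# brute-force gap splitter over a sorted vector of dates for one
# (patient, class): returns a data.frame of episode start/end
oracle_episodes <- function(dates, gap_days) {
  dates <- sort(unique(dates))
  starts <- dates[1]
  ends <- dates[1]
  for (d in as.list(dates[-1])) {
    if (as.numeric(d - ends[length(ends)]) >= gap_days) {
      starts <- c(starts, d)
      ends <- c(ends, d)
    } else {
      ends[length(ends)] <- d
    }
  }
  data.frame(start_date = starts, end_date = ends)
}

# hand-rolled linear-interpolation quantile (type 7) for oracle use
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# brute-force lowest-decile savings
oracle_savings <- function(cost, n_patients, p = 0.1) {
  b <- oracle_quantile7(cost, p)
  s <- 0
  for (i in seq_along(cost)) {
    if (cost[i] > b) s <- s + (cost[i] - b) * n_patients[i]
  }
  list(benchmark = b, saving = s)
}

# plain moment-formula excess kurtosis
oracle_kurtosis <- function(x) {
  m <- mean(x)
  mean((x - m)^4) / mean((x - m)^2)^2 - 3
}

# random small prescription histories (<= n_rx prescriptions over a
# limited class vocabulary, duplicate dates and combinations included)
random_history <- function(pid, n_rx = 6) {
  drugs <- c("metformin", "gliclazide", "sitagliptin",
             "Metformin Hydrochloride/sitagliptin", "gliclazide/sitagliptin")
  k <- sample.int(n_rx, 1)
  rx_tbl(
    patient_id = rep(pid, k),
    date = as.Date("2005-01-01") + sample.int(2000, k, replace = TRUE),
    drug_name = sample(drugs, k, replace = TRUE)
  )
}
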