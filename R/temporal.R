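#' Compute the analysis window for a phase of a hospital stay
#'
#' Admission windows are the 24 hours after admission, discharge windows the
#' 24 hours before discharge (stays under 24 h are excluded and counted);
#' the intermediate window is the calendar day containing the stay midpoint,
#' optionally widened by `mid_days` days on each side. Each window carries
#' the day type (weekday/weekend, Saturday and Sunday being the weekend) of
#' its anchor: the admission day, the discharge day, or the midpoint day.
#'
#' @param visits Tibble with `patient_id`, `admission`, `discharge`
#'   (`POSIXct`; see [read_visits()]).
#' @param phase `"admission"`, `"discharge"`, or `"intermediate"`.
#' @param mid_days Radius in days around the midpoint day for the
#'   intermediate phase (default 0: the single midpoint day).
#' @return Tibble `patient_id`, `window_start`, `window_end` (half-open
#'   `[start, end)`), `day_type`; the number of excluded short stays is
#'   attached as attribute `"n_excluded"`.
#' @export
phase_window <- function(visits, phase = c("admission", "discharge",
                                           "intermediate"),
                         mid_days = 0) {
  phase <- match.arg(phase)
  stopifnot(all(visits$admission < visits$discharge))
  h24 <- 86400
  if (phase %in% c("admission", "discharge")) {
    ok <- as.numeric(visits$discharge) - as.numeric(visits$admission) >= h24
    n_excluded <- sum(!ok)
    v <- visits[ok, , drop = FALSE]
    anchor <- if (phase == "admission") v$admission else v$discharge
    ws <- if (phase == "admission") anchor else anchor - h24
    out <- tibble::tibble(patient_id = v$patient_id,
                          window_start = ws, window_end = ws + h24,
                          day_type = day_type_of(anchor))
  } else {
    mid <- visits$admission +
      (as.numeric(visits$discharge) - as.numeric(visits$admission)) / 2
    mid_day <- floor(as.numeric(mid) / h24) * h24
    ws <- as.POSIXct(mid_day - mid_days * h24, origin = "1970-01-01",
                     tz = "UTC")
    out <- tibble::tibble(patient_id = visits$patient_id,
                          window_start = ws,
                          window_end = ws + (2 * mid_days + 1) * h24,
                          day_type = day_type_of(ws + mid_days * h24))
    n_excluded <- 0L
  }
  attr(out, "n_excluded") <- n_excluded
  out
}

# Saturday/Sunday of the (naive) calendar are the weekend
day_type_of <- function(t) {
  ifelse(format(t, "%u", tz = "UTC") %in% c("6", "7"), "weekend", "weekday")
}

#' Hourly concurrency profile for a patient group
#'
#' For every patient whose phase anchor falls on the requested day type,
#' counts the concurrent intervals starting in each of the 24 hourly slots
#' of the phase window — slots are offsets from the window start
#' (hours-since-admission, hours-until-discharge), not clock hours — and
#' averages the counts over the group's patients (patients with no
#' concurrent activity in the window contribute zeros). Multi-day
#' intermediate windows fold onto 24 slots and are averaged per day.
#'
#' @param labeled Intervals labeled by [label_intervals()] (only rows with
#'   `concurrent == TRUE` are counted).
#' @param visits Visit metadata (see [phase_window()]).
#' @param phase Phase of the hospital stay.
#' @param day_type `"weekday"` or `"weekend"`.
#' @param mid_days Passed to [phase_window()].
#' @param attribute `"start"` (default) counts an interval in the slot
#'   containing its start; `"overlap"` prorates it over slots by overlap
#'   seconds.
#' @return A `"temporal_pattern"` list: `phase`, `day_type`, `hours` (0-23),
#'   `mean_counts` (length 24), `n_patients`, `n_intervals` (total counted).
#' @export
hourly_pattern <- function(labeled, visits,
                           phase = c("admission", "discharge", "intermediate"),
                           day_type = c("weekday", "weekend"),
                           mid_days = 0, attribute = c("start", "overlap")) {
  phase <- match.arg(phase)
  day_type <- match.arg(day_type)
  attribute <- match.arg(attribute)
  win <- phase_window(visits, phase, mid_days)
  win <- win[win$day_type == day_type, , drop = FALSE]
  n_pat <- nrow(win)
  counts <- matrix(0, nrow = n_pat, ncol = 24)
  conc <- labeled[labeled$concurrent, , drop = FALSE]
  n_days <- as.numeric(win$window_end[1] - win$window_start[1],
                       units = "days")
  if (n_pat == 0) n_days <- 1
  total <- 0L
  for (i in seq_len(n_pat)) {
    iv <- conc[conc$patient_id == win$patient_id[i], , drop = FALSE]
    ws <- as.numeric(win$window_start[i])
    we <- as.numeric(win$window_end[i])
    if (attribute == "start") {
      t0 <- as.numeric(iv$start)
      inwin <- t0 >= ws & t0 < we
      slot <- floor(((t0[inwin] - ws) %% 86400) / 3600)
      if (length(slot) > 0) {
        tab <- tabulate(slot + 1, nbins = 24)
        counts[i, ] <- tab / n_days
        total <- total + length(slot)
      }
    } else {
      t0 <- pmax(as.numeric(iv$start), ws)
      t1 <- pmin(as.numeric(iv$stop), we)
      sel <- which(t1 > t0)
      for (j in sel) {
        edges <- ws + 3600 * (0:(24 * n_days))
        ov <- pmin(t1[j], edges[-1]) - pmax(t0[j], edges[-length(edges)])
        ov <- pmax(ov, 0)
        span <- t1[j] - t0[j]
        counts[i, ] <- counts[i, ] +
          rowSums(matrix(ov / span, nrow = 24)) / n_days
      }
      total <- total + length(sel)
    }
  }
  mean_counts <- if (n_pat > 0) colMeans(counts) else rep(0, 24)
  out <- list(phase = phase, day_type = day_type, hours = 0:23,
              mean_counts = mean_counts, n_patients = n_pat,
              n_intervals = total)
  class(out) <- "temporal_pattern"
  if (n_pat == 0) attr(out, "empty_group") <- TRUE
  out
}

#' @export
print.temporal_pattern <- function(x, ...) {
  cat(sprintf("Temporal pattern: %s phase, %s (%d patients, %d concurrent intervals)\n",
              x$phase, x$day_type, x$n_patients, x$n_intervals))
  cat(sprintf("  mean concurrent intervals/hour: %.2f\n", mean(x$mean_counts)))
  invisible(x)
}

#' Compare two hourly concurrency patterns
#'
#' Wilcoxon rank-sum test on the two 24-slot sequences (order-based, robust
#' to scale) and a Welch t test on their hourly means. Identical constant
#' patterns report p = 1 rather than failing.
#'
#' @param a,b `"temporal_pattern"` objects (or bare length-24 vectors).
#' @return Tibble with rows `wilcoxon` and `t`: `statistic`, `p_value`,
#'   `mean_a`, `mean_b`, `significant` (at .05).
#' @export
compare_patterns <- function(a, b) {
  va <- if (inherits(a, "temporal_pattern")) a$mean_counts else a
  vb <- if (inherits(b, "temporal_pattern")) b$mean_counts else b
  stopifnot(length(va) == 24, length(vb) == 24)
  w <- suppressWarnings(stats::wilcox.test(va, vb, exact = FALSE))
  wp <- w$p.value
  if (is.nan(wp)) wp <- 1  # all-tied sequences carry no order information
  tt <- tryCatch(stats::t.test(va, vb),
                 error = function(e) NULL)
  if (is.null(tt)) {
    # essentially-constant data: equal means are indistinguishable
    tstat <- if (mean(va) == mean(vb)) 0 else NA_real_
    tp <- if (mean(va) == mean(vb)) 1 else NA_real_
  } else {
    tstat <- unname(tt$statistic)
    tp <- tt$p.value
  }
  out <- tibble::tibble(
    test = c("wilcoxon", "t"),
    statistic = c(unname(w$statistic), tstat),
    p_value = c(wp, tp),
    mean_a = mean(va), mean_b = mean(vb))
  out$significant <- !is.na(out$p_value) & out$p_value < 0.05
  out
}
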