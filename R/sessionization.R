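#' Sessionize audit-log events into intervals
#'
#' An interval is a maximal run of one HCW's consecutive events on one
#' patient's record in which successive events are separated by at most
#' `cutoff` seconds; a gap strictly greater than the cutoff starts a new
#' interval. A single-event interval has duration 0. Intervals are the unit
#' of EHR "work" for everything downstream: workday filtering, concurrency
#' detection, intensity metrics.
#'
#' @param events Tibble of events sorted by `(hcw_id, patient_id, timestamp)`
#'   (see [read_events()]/[sort_events()]); unsorted input is an error.
#' @param cutoff Gap cutoff in seconds (> 0). A gap exactly equal to the
#'   cutoff stays within the interval.
#' @param keep_actions If `TRUE`, attach a list-column `actions` holding each
#'   interval's multiset of action labels (needed for action-composition
#'   clustering; off by default to keep large runs cheap).
#'
#' @return Tibble with one row per interval: `interval_id` (integer, in
#'   canonical event order), `hcw_id`, `patient_id`, `start`, `stop`
#'   (`POSIXct`), `duration` (seconds), `n_events`, and optionally `actions`.
#' @seealso [event_intervals()] for the per-event interval assignment,
#'   [estimate_cutoff()] for choosing `cutoff` from the data.
#' @export
build_intervals <- function(events, cutoff, keep_actions = FALSE) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0)
  iid <- interval_ids(events, cutoff)
  n <- nrow(events)
  if (n == 0) {
    out <- tibble::tibble(
      interval_id = integer(), hcw_id = character(), patient_id = character(),
      start = as.POSIXct(character(), tz = "UTC"),
      stop = as.POSIXct(character(), tz = "UTC"),
      duration = numeric(), n_events = integer())
    if (keep_actions) out$actions <- list()
    return(out)
  }
  first <- which(c(TRUE, iid[-1] != iid[-n]))
  last <- c(first[-1] - 1L, n)
  out <- tibble::tibble(
    interval_id = iid[first],
    hcw_id = events$hcw_id[first],
    patient_id = events$patient_id[first],
    start = events$timestamp[first],
    stop = events$timestamp[last],
    n_events = last - first + 1L)
  out$duration <- as.numeric(out$stop) - as.numeric(out$start)
  out <- out[, c("interval_id", "hcw_id", "patient_id", "start", "stop",
                 "duration", "n_events")]
  if (keep_actions) {
    out$actions <- unname(split(events$action_id, iid))
  }
  out
}

#' Assign each event to its interval
#'
#' Same segmentation as [build_intervals()], but returns the events
#' themselves with an `interval_id` column appended — the join key for the
#' interval-by-action matrix.
#'
#' @inheritParams build_intervals
#' @return `events` with an integer `interval_id` column.
#' @export
event_intervals <- function(events, cutoff) {
  events$interval_id <- interval_ids(events, cutoff)
  events
}

# Core segmentation: interval id per event. A new interval starts at every
# (hcw, patient) group boundary and at every within-group gap > cutoff.
interval_ids <- function(events, cutoff) {
  n <- nrow(events)
  if (n == 0) return(integer())
  if (!is_sorted_events(events)) {
    stop("events must be sorted by (hcw_id, patient_id, timestamp); ",
         "see sort_events()", call. = FALSE)
  }
  ts <- as.numeric(events$timestamp)
  new_group <- c(TRUE, events$hcw_id[-1] != events$hcw_id[-n] |
                   events$patient_id[-1] != events$patient_id[-n])
  gap <- c(Inf, ts[-1] - ts[-n])
  cumsum(new_group | gap > cutoff)
}

#' Discrete curvature of a sampled curve
#'
#' Evaluates the plane-curve curvature
#' \eqn{K(x) = f''(x) / (1 + f'(x)^2)^{1.5}} on a sampled function using
#' central finite differences (one-sided at the ends). For a parabola
#' \eqn{f(x) = x^2} this gives exactly 2 at the vertex.
#'
#' @param x Strictly increasing sample locations.
#' @param y Function values at `x`.
#' @return Numeric vector of curvature values, one per sample.
#' @export
discrete_curvature <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3, !is.unsorted(x))
  d1 <- finite_gradient(x, y)
  d2 <- finite_gradient(x, d1)
  d2 / (1 + d1^2)^1.5
}

# numpy-style gradient: central differences inside, one-sided at the ends
finite_gradient <- function(x, y) {
  n <- length(x)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    g[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  g
}

#' Find the knee (maximum-curvature point) of a trade-off curve
#'
#' Implements the Kneedle construction: smooth `y` with a centered moving
#' average, min-max normalize both axes to \[0, 1\], orient the curve to its
#' increasing form (flipping a decreasing `y`), and take the difference
#' between the curve and the diagonal. The knee is the `x` at the maximum of
#' that difference curve, which coincides with the point of maximum
#' curvature for the monotone convex/concave trade-off curves this package
#' produces (interval count vs. gap cutoff; within-cluster sum of squares
#' vs. k). Deterministic; ties resolve to the smallest `x` (the conservative
#' choice for sessionization).
#'
#' @param curve_x Strictly increasing candidate values (at least 5).
#' @param curve_y Response values.
#' @param smoothing Odd moving-average window width (default 5); 1 disables
#'   smoothing.
#' @return The selected `x`, with the inspected curve (columns `x`, `y`,
#'   `y_smooth`, `difference`) attached as attribute `"curve"` and the
#'   maximum normalized difference as attribute `"strength"` (values near 0
#'   indicate a weak, low-confidence knee).
#' @export
#' @examples
#' x <- seq(0, 10, by = 0.25)
#' y <- ifelse(x <= 2, 20 - 10 * x, -0.1 * (x - 2))
#' knee_point(x, y) # 2
knee_point <- function(curve_x, curve_y, smoothing = 5) {
  n <- length(curve_x)
  if (n < 5) stop("knee_point needs at least 5 points", call. = FALSE)
  stopifnot(length(curve_y) == n)
  if (any(diff(curve_x) <= 0)) {
    stop("curve_x must be strictly increasing", call. = FALSE)
  }
  ys <- moving_average(curve_y, smoothing)
  if (is.unsorted(ys) && is.unsorted(rev(ys))) {
    warning("curve is not monotone after smoothing; knee may be unreliable")
  }
  if (diff(range(ys)) == 0) {
    stop("no knee: curve is flat", call. = FALSE)
  }
  xn <- (curve_x - min(curve_x)) / diff(range(curve_x))
  yn <- (ys - min(ys)) / diff(range(ys))
  decreasing <- yn[n] < yn[1]
  if (decreasing) yn <- 1 - yn
  # increasing-concave curves sit above the diagonal; convex ones below
  concave <- mean(yn - xn) >= 0
  d <- if (concave) yn - xn else xn - yn
  if (max(d) <= 1e-6) {
    stop("no knee: curve has no curvature away from a straight line",
         call. = FALSE)
  }
  i <- which(d == max(d))[1]
  knee <- curve_x[i]
  attr(knee, "curve") <- tibble::tibble(
    x = curve_x, y = curve_y, y_smooth = ys, difference = d)
  # max difference (0..1 scale): near 0 means a weak, low-confidence knee
  attr(knee, "strength") <- max(d)
  knee
}

# centered moving average; windows shrink symmetrically near the edges so
# straight lines stay exactly straight (no spurious curvature at the ends)
moving_average <- function(y, window) {
  stopifnot(window >= 1)
  if (window %% 2 == 0) window <- window + 1
  if (window == 1 || length(y) < 3) return(y)
  h <- (window - 1) / 2
  n <- length(y)
  cs <- cumsum(c(0, y))
  hs <- pmin(h, seq_len(n) - 1, n - seq_len(n))
  lo <- seq_len(n) - hs
  hi <- seq_len(n) + hs
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Estimate the gap cutoff from the interval-count curve
#'
#' Computes, for each candidate cutoff `c`, the number of intervals
#' [build_intervals()] would produce (equal to the number of
#' `(hcw, patient)` groups plus the number of within-group gaps exceeding
#' `c` — evaluated directly from the gap distribution so the scan is cheap),
#' then returns the knee of this decreasing curve via [knee_point()]. The
#' knee marks the cutoff separating the within-task gap scale (seconds to a
#' couple of minutes) from the between-task scale (tens of minutes).
#'
#' @inheritParams build_intervals
#' @param candidate_cutoffs Ascending candidate cutoffs in seconds. The
#'   default grid 10–1800 s in 10 s steps spans both gap scales seen in
#'   EHR audit logs.
#' @param smoothing Passed to [knee_point()].
#' @return Selected cutoff in seconds, with the interval-count curve attached
#'   as attribute `"curve"` for inspection.
#' @export
estimate_cutoff <- function(events,
                            candidate_cutoffs = seq(10, 1800, by = 10),
                            smoothing = 5) {
  stopifnot(!is.unsorted(candidate_cutoffs))
  if (!is_sorted_events(events)) {
    stop("events must be sorted by (hcw_id, patient_id, timestamp)",
         call. = FALSE)
  }
  n <- nrow(events)
  if (n == 0) stop("no events", call. = FALSE)
  ts <- as.numeric(events$timestamp)
  new_group <- c(TRUE, events$hcw_id[-1] != events$hcw_id[-n] |
                   events$patient_id[-1] != events$patient_id[-n])
  n_groups <- sum(new_group)
  gaps <- sort((ts[-1] - ts[-n])[!new_group[-1]])
  # intervals at cutoff c = groups + #{gaps > c}; findInterval counts <= c
  y <- n_groups + length(gaps) - findInterval(candidate_cutoffs, gaps)
  knee_point(candidate_cutoffs, y, smoothing = smoothing)
}

#' Flag active EHR workdays
#'
#' Sums each HCW's interval durations per calendar day and flags the day
#' active when the total meets the workday cutoff (15 minutes in a NICU
#' setting; the right value depends on the clinical environment). Days below
#' the cutoff are "inactive EHR workdays" and are excluded from intensity
#' metrics. Intervals crossing midnight contribute to each day the part of
#' their duration that falls in it.
#'
#' @param intervals Output of [build_intervals()].
#' @param workday_cutoff Minimum summed interval duration, in minutes, for a
#'   day to count as active (default 15).
#' @return Tibble with one row per `(hcw_id, date)` having any activity:
#'   `hcw_id`, `date` (`Date`), `ehr_time` (minutes), `active` (logical).
#' @export
flag_workdays <- function(intervals, workday_cutoff = 15) {
  stopifnot(workday_cutoff > 0)
  pieces <- split_interval_days(intervals)
  out <- dplyr::summarise(
    dplyr::group_by(pieces, .data$hcw_id, .data$date),
    ehr_time = sum(.data$seconds) / 60, .groups = "drop")
  out$active <- out$ehr_time >= workday_cutoff
  out
}

# Explode intervals into per-calendar-day pieces. Columns: all interval
# columns except start/stop/duration, plus date and seconds (that day's
# share of the duration). Zero-duration intervals keep one piece with 0 s.
split_interval_days <- function(intervals) {
  day <- 86400
  t0 <- as.numeric(intervals$start)
  t1 <- as.numeric(intervals$stop)
  d0 <- floor(t0 / day)
  d1 <- floor(t1 / day)
  # stop exactly at midnight belongs to the earlier day
  d1 <- ifelse(d1 > d0 & t1 == d1 * day, d1 - 1, d1)
  n_days <- d1 - d0 + 1
  idx <- rep.int(seq_len(nrow(intervals)), n_days)
  dayn <- d0[idx] + (sequence(n_days) - 1)
  piece_start <- pmax(t0[idx], dayn * day)
  piece_stop <- pmin(t1[idx], (dayn + 1) * day)
  keep <- setdiff(names(intervals), c("start", "stop", "duration", "actions"))
  pieces <- intervals[idx, keep, drop = FALSE]
  pieces$date <- as.Date(dayn, origin = "1970-01-01")
  pieces$seconds <- piece_stop - piece_start
  tibble::as_tibble(pieces)
}
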