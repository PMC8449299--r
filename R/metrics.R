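#' Compute per-HCW daily concurrent intensity
#'
#' Concurrent intensity quantifies how much of an HCW's EHR work happens
#' simultaneously with other HCWs on the same patient: per active workday,
#' the proportion of intervals that are concurrent and the proportion of EHR
#' time spent in concurrent intervals. A concurrent interval contributes its
#' full duration (partial overlap is not prorated). Inactive EHR workdays
#' are excluded. Midnight-crossing intervals are split across days exactly
#' as in [flag_workdays()], so daily `ehr_time` here always reconciles with
#' the workday table.
#'
#' @param labeled Intervals labeled by [label_intervals()].
#' @param workdays Output of [flag_workdays()] on the same intervals.
#' @return Tibble with one row per active `(hcw_id, date)`: `n_intervals`,
#'   `n_concurrent`, `ehr_time` and `concurrent_time` (minutes),
#'   `n_actions` (events in intervals starting that day), `prop_intervals`,
#'   `prop_time`.
#' @export
compute_intensity <- function(labeled, workdays) {
  if (!"concurrent" %in% names(labeled)) {
    stop("intervals must be labeled; see label_intervals()", call. = FALSE)
  }
  pieces <- split_interval_days(labeled)
  day <- dplyr::summarise(
    dplyr::group_by(pieces, .data$hcw_id, .data$date),
    n_intervals = dplyr::n(),
    n_concurrent = sum(.data$concurrent),
    ehr_time = sum(.data$seconds) / 60,
    concurrent_time = sum(.data$seconds[.data$concurrent]) / 60,
    .groups = "drop")
  acts <- dplyr::summarise(
    dplyr::group_by(labeled, .data$hcw_id,
                    date = as.Date(.data$start, tz = "UTC")),
    n_actions = sum(.data$n_events), .groups = "drop")
  day <- dplyr::left_join(day, acts, by = c("hcw_id", "date"))
  day$n_actions[is.na(day$n_actions)] <- 0L
  active <- workdays[workdays$active, c("hcw_id", "date", "ehr_time")]
  rec <- dplyr::inner_join(day, active, by = c("hcw_id", "date"),
                           suffix = c("", ".wd"))
  if (any(abs(rec$ehr_time - rec$ehr_time.wd) > 1e-8) ||
      any(rec$ehr_time <= 0)) {
    stop("inconsistent workday table: active day with mismatched or zero ",
         "EHR time", call. = FALSE)
  }
  rec$ehr_time.wd <- NULL
  rec$prop_intervals <- rec$n_concurrent / rec$n_intervals
  rec$prop_time <- rec$concurrent_time / rec$ehr_time
  rec
}

#' Summarize intensity by specialty
#'
#' Two-stage aggregation: per-HCW means over their active days first, then
#' specialty mean and 95% CI over HCWs (so HCWs with many recorded days do
#' not dominate their specialty). CIs use the t distribution on the per-HCW
#' means; a specialty with a single HCW gets `NA` bounds. Specialties are
#' ranked by mean daily EHR time and the top `top_k` kept.
#'
#' @param records Output of [compute_intensity()].
#' @param hcw_meta Tibble with `hcw_id`, `specialty` (see [read_hcw_meta()]).
#' @param top_k Number of specialties to keep (default 13); `Inf` keeps all.
#' @return Tibble with one row per specialty: `n_hcws` and
#'   mean/`ci_lo`/`ci_hi` for `ehr_time`, `n_actions`, `prop_intervals`,
#'   `prop_time`.
#' @export
summarize_by_specialty <- function(records, hcw_meta, top_k = 13) {
  per_hcw <- hcw_means(records, hcw_meta)
  if (nrow(per_hcw) == 0) stop("no records join the metadata", call. = FALSE)
  ci_cols <- function(x, prefix) {
    n <- length(x)
    m <- mean(x)
    half <- if (n < 2) NA_real_
    else if (stats::sd(x) == 0) 0
    else stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n)
    out <- tibble::tibble(m, m - half, m + half)
    names(out) <- c(prefix, paste0(prefix, "_lo"), paste0(prefix, "_hi"))
    out
  }
  out <- dplyr::group_modify(
    dplyr::group_by(per_hcw, .data$specialty), function(d, key) {
      dplyr::bind_cols(
        tibble::tibble(n_hcws = nrow(d)),
        ci_cols(d$ehr_time, "ehr_time"),
        ci_cols(d$n_actions, "n_actions"),
        ci_cols(d$prop_intervals, "prop_intervals"),
        ci_cols(d$prop_time, "prop_time"))
    })
  out <- dplyr::ungroup(out)
  out <- dplyr::arrange(out, dplyr::desc(.data$ehr_time))
  utils::head(out, top_k)
}

# per-HCW means over active days, joined with specialty
hcw_means <- function(records, hcw_meta) {
  per_hcw <- dplyr::summarise(
    dplyr::group_by(records, .data$hcw_id),
    ehr_time = mean(.data$ehr_time),
    n_actions = mean(.data$n_actions),
    prop_intervals = mean(.data$prop_intervals),
    prop_time = mean(.data$prop_time),
    .groups = "drop")
  dplyr::inner_join(per_hcw, hcw_meta[, c("hcw_id", "specialty")],
                    by = "hcw_id")
}

#' Compare concurrent intensity across specialties
#'
#' One-way ANOVA of daily EHR time and both intensity proportions across
#' specialties (per-HCW means as observations), plus a per-specialty
#' Spearman rank correlation between daily EHR time and daily concurrent
#' time (are an HCW's heavier EHR days also their more concurrent days?).
#' Significance is flagged at the two-sided .05 level.
#'
#' @inheritParams summarize_by_specialty
#' @return List with `anova` (metric, f, p_value, significant) and
#'   `spearman` (specialty, n_days, rho, p_value, significant). Degenerate
#'   inputs (zero variance) yield non-finite statistics rather than errors.
#' @export
compare_specialties <- function(records, hcw_meta) {
  per_hcw <- hcw_means(records, hcw_meta)
  sizes <- table(per_hcw$specialty)
  if (sum(sizes >= 2) < 2) {
    stop("need at least 2 specialties with at least 2 HCWs each",
         call. = FALSE)
  }
  anova_row <- function(metric) {
    df <- data.frame(y = per_hcw[[metric]],
                     g = factor(per_hcw$specialty))
    # degenerate (zero-variance) metrics yield non-finite statistics; the
    # values are reported as-is rather than warned about
    tab <- suppressWarnings(stats::anova(stats::aov(y ~ g, data = df)))
    tibble::tibble(metric = metric, f = tab$`F value`[1],
                   p_value = tab$`Pr(>F)`[1])
  }
  av <- dplyr::bind_rows(lapply(
    c("ehr_time", "prop_intervals", "prop_time"), anova_row))
  av$significant <- !is.na(av$p_value) & av$p_value < 0.05

  rec <- dplyr::inner_join(records, hcw_meta[, c("hcw_id", "specialty")],
                           by = "hcw_id")
  sp <- dplyr::group_modify(
    dplyr::group_by(rec, .data$specialty), function(d, key) {
      if (nrow(d) < 3 || stats::sd(d$ehr_time) == 0 ||
          stats::sd(d$concurrent_time) == 0) {
        return(tibble::tibble(n_days = nrow(d), rho = NA_real_,
                              p_value = NA_real_))
      }
      ct <- suppressWarnings(stats::cor.test(
        d$ehr_time, d$concurrent_time, method = "spearman", exact = FALSE))
      tibble::tibble(n_days = nrow(d), rho = unname(ct$estimate),
                     p_value = ct$p.value)
    })
  sp <- dplyr::ungroup(sp)
  sp$significant <- !is.na(sp$p_value) & sp$p_value < 0.05
  list(anova = av, spearman = sp)
}
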