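#' Run the sessionization-to-network pipeline on an event stream
#'
#' Convenience wrapper chaining the core stages: estimate (or accept) the
#' gap cutoff, build intervals, flag workdays, detect overlaps, assemble
#' concurrent sessions, label intervals, and build the intermediate
#' matrices.
#'
#' @param events Sorted events (see [read_events()] / [sort_events()]).
#' @param cutoff Gap cutoff in seconds, or `NULL` to estimate it with
#'   [estimate_cutoff()].
#' @param workday_cutoff Active-workday threshold in minutes (default 15).
#' @param session_rule Passed to [assemble_sessions()].
#' @param candidate_cutoffs Passed to [estimate_cutoff()] when `cutoff` is
#'   `NULL`.
#' @return List: `cutoff`, `intervals` (labeled), `workdays`, `pairs`,
#'   `sessions`, `matrices` (includes `interval_action`: events are
#'   re-segmented with [event_intervals()] internally).
#' @export
collaboration_pipeline <- function(events, cutoff = NULL,
                                   workday_cutoff = 15,
                                   session_rule = "component",
                                   candidate_cutoffs = seq(10, 1800, by = 10)) {
  if (is.null(cutoff)) {
    cutoff <- as.numeric(estimate_cutoff(events, candidate_cutoffs))
  }
  intervals <- build_intervals(events, cutoff)
  workdays <- flag_workdays(intervals, workday_cutoff)
  pairs <- find_overlap_pairs(intervals)
  sessions <- assemble_sessions(pairs, intervals, rule = session_rule)
  labeled <- label_intervals(intervals, sessions)
  ev_iid <- event_intervals(events, cutoff)
  matrices <- build_matrices(labeled, sessions, events = ev_iid)
  list(cutoff = cutoff, intervals = labeled, workdays = workdays,
       pairs = pairs, sessions = sessions, matrices = matrices)
}
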