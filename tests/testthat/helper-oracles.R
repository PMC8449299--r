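# Shared fixtures and independent brute-force oracles.

T0 <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

# events from numeric offsets (seconds since T0)
ev_tbl <- function(hcw, patient, t, action = "A") {
  tb <- tibble::tibble(hcw_id = as.character(hcw),
                       patient_id = as.character(patient),
                       action_id = rep_len(as.character(action), length(t)),
                       timestamp = T0 + t)
  sort_events(tb)
}

# intervals from numeric offsets
int_tbl <- function(hcw, patient, start, stop) {
  tibble::tibble(interval_id = seq_along(start),
                 hcw_id = as.character(hcw),
                 patient_id = as.character(patient),
                 start = T0 + start, stop = T0 + stop,
                 duration = as.numeric(stop - start),
                 n_events = 1L)
}

# the two-HCW worked example shipped with the package
example_events <- function() {
  read_events(system.file("extdata", "example_events.csv",
                          package = "ehrcollab"))
}

# random event stream: n events over n_hcws x n_patients groups with
# two-scale exponential gaps
random_stream <- function(n, n_hcws = 3, n_patients = 3,
                          within = 20, between = 600, p_break = 0.2) {
  hcw <- sprintf("h%d", sample.int(n_hcws, n, replace = TRUE))
  pat <- sprintf("p%d", sample.int(n_patients, n, replace = TRUE))
  gaps <- ifelse(stats::runif(n) < p_break,
                 stats::rexp(n, 1 / between), stats::rexp(n, 1 / within))
  t <- round(cumsum(gaps))
  ev_tbl(hcw, pat, t)
}

# naive per-group linear scan: interval id per event
oracle_interval_ids <- function(events, cutoff) {
  n <- nrow(events)
  out <- integer(n)
  cur <- 0L
  ts <- as.numeric(events$timestamp)
  for (i in seq_len(n)) {
    new_grp <- i == 1 || events$hcw_id[i] != events$hcw_id[i - 1] ||
      events$patient_id[i] != events$patient_id[i - 1]
    if (new_grp || ts[i] - ts[i - 1] > cutoff) cur <- cur + 1L
    out[i] <- cur
  }
  out
}

# O(n^2) all-pairs positive-overlap detection
oracle_pairs <- function(intervals) {
  n <- nrow(intervals)
  if (n < 2) {
    return(tibble::tibble(interval_a = integer(), interval_b = integer(),
                          overlap = numeric()))
  }
  idx <- t(utils::combn(n, 2))
  i <- idx[, 1]; j <- idx[, 2]
  ov <- pmin(as.numeric(intervals$stop[i]), as.numeric(intervals$stop[j])) -
    pmax(as.numeric(intervals$start[i]), as.numeric(intervals$start[j]))
  keep <- intervals$patient_id[i] == intervals$patient_id[j] &
    intervals$hcw_id[i] != intervals$hcw_id[j] & ov > 0
  out <- tibble::tibble(
    interval_a = pmin(intervals$interval_id[i], intervals$interval_id[j])[keep],
    interval_b = pmax(intervals$interval_id[i], intervals$interval_id[j])[keep],
    overlap = ov[keep])
  dplyr::arrange(out, interval_a, interval_b)
}

# brute-force transitive closure into connected components
oracle_components <- function(pairs, ids) {
  comp <- stats::setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(pairs))) {
      a <- as.character(pairs$interval_a[r])
      b <- as.character(pairs$interval_b[r])
      if (comp[a] != comp[b]) {
        comp[comp == comp[b]] <- comp[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# iterative-deletion k-core on an adjacency matrix
oracle_kcore_nodes <- function(adj, k) {
  alive <- rep(TRUE, nrow(adj))
  repeat {
    deg <- rowSums(adj[, alive, drop = FALSE] > 0)[alive]
    drop <- names(deg)[deg < k]
    drop_idx <- which(alive)[deg < k]
    if (length(drop_idx) == 0) break
    alive[drop_idx] <- FALSE
    if (!any(alive)) break
  }
  rownames(adj)[alive]
}

# per-session distinct-cluster count by explicit set union
oracle_complexity <- function(assignments, interval_session) {
  vapply(seq_len(ncol(interval_session)), function(s) {
    members <- rownames(interval_session)[interval_session[, s] > 0]
    length(unique(assignments[members]))
  }, numeric(1))
}
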