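#' Find positively overlapping interval pairs
#'
#' Two intervals are concurrent candidates when they are on the same
#' patient, by different HCWs, and their spans overlap by strictly more
#' than zero seconds (`min(stop) - max(start) > 0`); touching endpoints do
#' not count. Implemented as a per-patient sweep over start-sorted
#' intervals, so the cost is near-linear plus the number of reported pairs.
#'
#' @param intervals Tibble from [build_intervals()] (needs `interval_id`,
#'   `hcw_id`, `patient_id`, `start`, `stop`).
#' @return Tibble with one row per overlapping pair: `patient_id`,
#'   `interval_a`, `interval_b` (interval ids, `a < b`), `overlap` (seconds).
#' @export
find_overlap_pairs <- function(intervals) {
  res <- lapply(split(seq_len(nrow(intervals)), intervals$patient_id),
                function(ix) {
    m <- length(ix)
    if (m < 2) return(NULL)
    o <- ix[order(as.numeric(intervals$start[ix]), intervals$interval_id[ix])]
    st <- as.numeric(intervals$start[o])
    en <- as.numeric(intervals$stop[o])
    hcw <- intervals$hcw_id[o]
    id <- intervals$interval_id[o]
    acc <- vector("list", m)
    for (i in seq_len(m - 1)) {
      # starts are sorted: candidates are the j > i with st[j] < en[i]
      hi <- findInterval(en[i], st)
      if (hi <= i) next
      js <- (i + 1):hi
      w <- pmin(en[i], en[js]) - st[js]
      keep <- w > 0 & hcw[js] != hcw[i]
      if (any(keep)) {
        js <- js[keep]
        acc[[i]] <- tibble::tibble(
          interval_a = pmin(id[i], id[js]), interval_b = pmax(id[i], id[js]),
          overlap = w[keep])
      }
    }
    pairs <- dplyr::bind_rows(acc)
    if (nrow(pairs) == 0) return(NULL)
    pairs$patient_id <- intervals$patient_id[o[1]]
    pairs
  })
  res <- dplyr::bind_rows(res)
  if (nrow(res) == 0) {
    return(tibble::tibble(patient_id = character(), interval_a = integer(),
                          interval_b = integer(), overlap = numeric()))
  }
  res <- res[, c("patient_id", "interval_a", "interval_b", "overlap")]
  dplyr::arrange(res, .data$patient_id, .data$interval_a, .data$interval_b)
}

#' Assemble concurrent sessions from overlap pairs
#'
#' A concurrent session is a set of temporally overlapping intervals on one
#' patient by at least two distinct HCWs. Under the default `"component"`
#' rule a session is a connected component of the pairwise-overlap graph
#' (overlap may be transitive: A overlaps B, B overlaps C links A and C even
#' if A and C never overlap directly). The `"clique"` rule instead splits
#' each patient's concurrent intervals into groups that all share a common
#' instant (for intervals on a line, pairwise overlap within a group is
#' equivalent to a shared instant), assigning greedily in start order;
#' groups left with a single member revert to individual intervals.
#'
#' @param pairs Output of [find_overlap_pairs()].
#' @param intervals The interval tibble the pairs were computed from.
#' @param rule `"component"` (default) or `"clique"`.
#' @return Membership tibble with one row per member interval: `session_id`,
#'   `patient_id`, `interval_id`, `hcw_id`, `start`, `stop`. Session ids are
#'   deterministic: `patient_id`, the session's earliest start, and a
#'   per-patient rank in start order.
#' @export
assemble_sessions <- function(pairs, intervals, rule = c("component", "clique")) {
  rule <- match.arg(rule)
  empty <- tibble::tibble(session_id = character(), patient_id = character(),
                          interval_id = integer(), hcw_id = character(),
                          start = intervals$start[0], stop = intervals$stop[0])
  if (nrow(pairs) == 0) return(empty)
  conc_ids <- sort(unique(c(pairs$interval_a, pairs$interval_b)))
  idx <- match(conc_ids, intervals$interval_id)
  if (anyNA(idx)) stop("pairs reference intervals not present", call. = FALSE)
  if (rule == "component") {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(pairs$interval_a),
                 to = as.character(pairs$interval_b)),
      directed = FALSE,
      vertices = data.frame(name = as.character(conc_ids)))
    grp <- igraph::components(g)$membership[as.character(conc_ids)]
    members <- tibble::tibble(
      interval_id = conc_ids, group = as.integer(grp),
      patient_id = intervals$patient_id[idx], hcw_id = intervals$hcw_id[idx],
      start = intervals$start[idx], stop = intervals$stop[idx])
  } else {
    members <- tibble::tibble(
      interval_id = conc_ids, group = NA_integer_,
      patient_id = intervals$patient_id[idx], hcw_id = intervals$hcw_id[idx],
      start = intervals$start[idx], stop = intervals$stop[idx])
    gshift <- 0L
    for (p in unique(members$patient_id)) {
      sel <- which(members$patient_id == p)
      sel <- sel[order(as.numeric(members$start[sel]), members$interval_id[sel])]
      cur <- 0L; min_stop <- -Inf
      for (i in sel) {
        s <- as.numeric(members$start[i])
        if (s < min_stop) {
          min_stop <- min(min_stop, as.numeric(members$stop[i]))
        } else {
          cur <- cur + 1L
          min_stop <- as.numeric(members$stop[i])
        }
        members$group[i] <- gshift + cur
      }
      gshift <- gshift + cur
    }
    sizes <- table(members$group)
    members <- members[members$group %in%
                         as.integer(names(sizes)[sizes >= 2]), , drop = FALSE]
    if (nrow(members) == 0) return(empty)
  }
  # deterministic ids: rank sessions within each patient by earliest start
  key <- dplyr::summarise(
    dplyr::group_by(members, .data$patient_id, .data$group),
    first_start = min(.data$start), first_id = min(.data$interval_id),
    .groups = "drop")
  key <- dplyr::arrange(key, .data$patient_id, .data$first_start, .data$first_id)
  key <- dplyr::mutate(dplyr::group_by(key, .data$patient_id),
                       rank = dplyr::row_number())
  key <- dplyr::ungroup(key)
  key$session_id <- sprintf("%s/%s/%d", key$patient_id,
                            format(key$first_start, "%Y%m%d%H%M%S", tz = "UTC"),
                            key$rank)
  members <- dplyr::left_join(members, key[, c("patient_id", "group", "session_id")],
                              by = c("patient_id", "group"))
  out <- dplyr::arrange(
    members[, c("session_id", "patient_id", "interval_id", "hcw_id",
                "start", "stop")],
    .data$patient_id, .data$session_id, .data$start, .data$interval_id)
  out
}

#' Summarize sessions (one row per session)
#'
#' @param sessions Membership tibble from [assemble_sessions()].
#' @return Tibble: `session_id`, `patient_id`, `n_intervals`, `n_hcws`,
#'   `span_start`, `span_stop`.
#' @export
session_summary <- function(sessions) {
  dplyr::summarise(
    dplyr::group_by(sessions, .data$session_id, .data$patient_id),
    n_intervals = dplyr::n(),
    n_hcws = dplyr::n_distinct(.data$hcw_id),
    span_start = min(.data$start), span_stop = max(.data$stop),
    .groups = "drop")
}

#' Label intervals as concurrent or individual
#'
#' A concurrent interval belongs to some concurrent session; an individual
#' interval belongs to none.
#'
#' @param intervals Tibble from [build_intervals()].
#' @param sessions Membership tibble from [assemble_sessions()].
#' @return `intervals` with `concurrent` (logical) and `session_id`
#'   (`NA` for individual intervals); counts of each class are attached as
#'   attribute `"label_report"`.
#' @export
label_intervals <- function(intervals, sessions) {
  m <- match(intervals$interval_id, sessions$interval_id)
  intervals$session_id <- sessions$session_id[m]
  intervals$concurrent <- !is.na(m)
  attr(intervals, "label_report") <- tibble::tibble(
    n_concurrent = sum(intervals$concurrent),
    n_individual = sum(!intervals$concurrent))
  intervals
}

#' Build the intermediate sparse matrices
#'
#' Assembles the cross-tabulations connecting concurrent intervals, actions,
#' sessions and HCWs that the downstream analyses consume:
#' * `interval_action` — concurrent interval x action, event counts;
#' * `interval_session` — concurrent interval x session, 0/1 membership;
#' * `hcw_session` — HCW x session, 0/1 participation;
#' * `hcw_interval` — HCW x concurrent interval, 0/1 ownership;
#' * `hcw_session_dur`, `hcw_interval_dur` — duration-weighted (seconds)
#'   variants of the previous two.
#'
#' @param labeled Output of [label_intervals()].
#' @param sessions Membership tibble from [assemble_sessions()].
#' @param events Optional events with `interval_id` (from
#'   [event_intervals()]); required for `interval_action` unless `labeled`
#'   carries an `actions` list-column.
#' @return List of `Matrix::sparseMatrix` objects with dimnames, classed
#'   `"ehr_matrix_set"`.
#' @export
build_matrices <- function(labeled, sessions, events = NULL) {
  conc <- labeled[labeled$concurrent, , drop = FALSE]
  int_ids <- as.character(conc$interval_id)
  sess_ids <- sort(unique(sessions$session_id))
  hcw_ids <- sort(unique(conc$hcw_id))

  # interval x action counts
  if (!is.null(events)) {
    ev <- events[events$interval_id %in% conc$interval_id, , drop = FALSE]
    acts <- sort(unique(ev$action_id))
    interval_action <- Matrix::sparseMatrix(
      i = match(as.character(ev$interval_id), int_ids),
      j = match(ev$action_id, acts),
      x = 1, dims = c(length(int_ids), length(acts)),
      dimnames = list(int_ids, acts))
  } else if ("actions" %in% names(conc)) {
    acts_flat <- unlist(conc$actions, use.names = FALSE)
    rep_i <- rep.int(seq_len(nrow(conc)), lengths(conc$actions))
    acts <- sort(unique(acts_flat))
    interval_action <- Matrix::sparseMatrix(
      i = rep_i, j = match(acts_flat, acts), x = 1,
      dims = c(length(int_ids), length(acts)),
      dimnames = list(int_ids, acts))
  } else {
    interval_action <- NULL
  }

  si <- match(conc$session_id, sess_ids)
  interval_session <- Matrix::sparseMatrix(
    i = seq_len(nrow(conc)), j = si, x = 1,
    dims = c(length(int_ids), length(sess_ids)),
    dimnames = list(int_ids, sess_ids))
  hi <- match(conc$hcw_id, hcw_ids)
  hcw_session <- Matrix::sparseMatrix(
    i = hi, j = si, x = 1, use.last.ij = TRUE,
    dims = c(length(hcw_ids), length(sess_ids)),
    dimnames = list(hcw_ids, sess_ids))
  hcw_session@x[] <- 1  # participation is 0/1 even with several intervals
  hcw_interval <- Matrix::sparseMatrix(
    i = hi, j = seq_len(nrow(conc)), x = 1,
    dims = c(length(hcw_ids), length(int_ids)),
    dimnames = list(hcw_ids, int_ids))
  hcw_session_dur <- Matrix::sparseMatrix(
    i = hi, j = si, x = conc$duration,
    dims = c(length(hcw_ids), length(sess_ids)),
    dimnames = list(hcw_ids, sess_ids))
  hcw_interval_dur <- Matrix::sparseMatrix(
    i = hi, j = seq_len(nrow(conc)), x = conc$duration,
    dims = c(length(hcw_ids), length(int_ids)),
    dimnames = list(hcw_ids, int_ids))

  structure(list(interval_action = interval_action,
                 interval_session = interval_session,
                 hcw_session = hcw_session,
                 hcw_interval = hcw_interval,
                 hcw_session_dur = hcw_session_dur,
                 hcw_interval_dur = hcw_interval_dur),
            class = "ehr_matrix_set")
}

#' Write a matrix set as sparse triplet CSV files
#'
#' Each matrix becomes `<name>.csv` with columns `row_id,col_id,value`
#' (dimnames as ids); readable back with [read_matrix_set()].
#'
#' @param matrices An `"ehr_matrix_set"` from [build_matrices()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_matrix_set <- function(matrices, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(matrices)) {
    m <- matrices[[nm]]
    if (is.null(m)) next
    tr <- Matrix::summary(m)
    df <- data.frame(row_id = rownames(m)[tr$i], col_id = colnames(m)[tr$j],
                     value = tr$x)
    # keep dims recoverable even when a row/col is all-zero
    hdr <- data.frame(row_id = "#dims", col_id = paste(dim(m), collapse = "x"),
                      value = NA_real_)
    readr::write_csv(rbind(hdr, df), file.path(dir, paste0(nm, ".csv")),
                     progress = FALSE)
    readr::write_csv(data.frame(axis = c(rep("row", nrow(m)), rep("col", ncol(m))),
                                index = c(seq_len(nrow(m)), seq_len(ncol(m))),
                                id = c(rownames(m), colnames(m))),
                     file.path(dir, paste0(nm, ".index.csv")), progress = FALSE)
  }
  invisible(dir)
}

#' Read a matrix set written by [write_matrix_set()]
#'
#' @param dir Directory holding the triplet CSVs.
#' @return An `"ehr_matrix_set"` list of sparse matrices.
#' @export
read_matrix_set <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[!grepl("\\.index\\.csv$", files)]
  out <- list()
  for (f in files) {
    nm <- sub("\\.csv$", "", basename(f))
    tr <- readr::read_csv(f, col_types = "ccd", progress = FALSE)
    idx <- readr::read_csv(sub("\\.csv$", ".index.csv", f),
                           col_types = "cic", progress = FALSE)
    rn <- idx$id[idx$axis == "row"]
    cn <- idx$id[idx$axis == "col"]
    tr <- tr[tr$row_id != "#dims", , drop = FALSE]
    out[[nm]] <- Matrix::sparseMatrix(
      i = match(tr$row_id, rn), j = match(tr$col_id, cn), x = tr$value,
      dims = c(length(rn), length(cn)), dimnames = list(rn, cn))
  }
  structure(out, class = "ehr_matrix_set")
}
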