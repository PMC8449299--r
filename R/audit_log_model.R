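#' Read audit-log events from a delimited text file
#'
#' Loads one EHR audit-log table: one row per event, i.e. one action an HCW
#' performed on one patient's record at one point in time. Rows with missing
#' identifiers, empty action labels, or unparseable timestamps are dropped
#' (and counted); the surviving events are sorted by
#' `(hcw_id, patient_id, timestamp)` with ties kept in file order, which is
#' the ordering every downstream sessionization step assumes.
#'
#' Timestamps are treated as naive local clock time: they are parsed in a
#' fixed zone (default `"UTC"`), so daylight-saving transitions are not
#' corrected and may appear as 1-hour gaps or overlaps in the raw log.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param column_map Named character vector mapping the canonical names
#'   `hcw_id`, `patient_id`, `action_id`, `timestamp` to the column names
#'   used in the file. Defaults to the identity mapping.
#' @param timestamp_format `strptime()` format string for the timestamp
#'   column. The default `"%m/%d/%Y %H:%M:%S"` matches logs printed as
#'   `4/5/2020 2:14:25`.
#' @param delim Field delimiter; `","` by default.
#' @param tz Time zone used to interpret the clock times (a fixed zone keeps
#'   arithmetic free of DST jumps).
#'
#' @return A tibble of events with columns `hcw_id`, `patient_id`,
#'   `action_id` (character) and `timestamp` (`POSIXct`), sorted as above.
#'   The attribute `"load_report"` holds a one-row tibble with
#'   `rows_read`, `rows_kept`, `rows_dropped`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "hcw_id,patient_id,action_id,timestamp",
#'   "A,1,FLOWSHEETS DATA SAVED,4/5/2020 2:14:25",
#'   "A,1,CHART REVIEW,4/5/2020 2:15:00"), f)
#' ev <- read_events(f)
#' attr(ev, "load_report")
read_events <- function(path,
                        column_map = c(hcw_id = "hcw_id",
                                       patient_id = "patient_id",
                                       action_id = "action_id",
                                       timestamp = "timestamp"),
                        timestamp_format = "%m/%d/%Y %H:%M:%S",
                        delim = ",",
                        tz = "UTC") {
  if (!file.exists(path)) {
    stop("event file does not exist: ", path, call. = FALSE)
  }
  needed <- c("hcw_id", "patient_id", "action_id", "timestamp")
  missing_map <- setdiff(needed, names(column_map))
  if (length(missing_map) > 0) {
    stop("column_map must name: ", paste(missing_map, collapse = ", "),
         call. = FALSE)
  }
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  absent <- setdiff(unname(column_map[needed]), names(raw))
  if (length(absent) > 0) {
    stop("mapped columns not present in file: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  rows_read <- nrow(raw)
  ev <- tibble::tibble(
    hcw_id = raw[[column_map[["hcw_id"]]]],
    patient_id = raw[[column_map[["patient_id"]]]],
    action_id = raw[[column_map[["action_id"]]]],
    timestamp = as.POSIXct(raw[[column_map[["timestamp"]]]],
                           format = timestamp_format, tz = tz)
  )
  keep <- !is.na(ev$timestamp) &
    !is.na(ev$hcw_id) & nzchar(ev$hcw_id) &
    !is.na(ev$patient_id) & nzchar(ev$patient_id) &
    !is.na(ev$action_id) & nzchar(ev$action_id)
  dropped <- sum(!keep)
  if (rows_read > 0 && dropped > rows_read / 2) {
    stop("more than 50% of rows were dropped (", dropped, "/", rows_read,
         "); check timestamp_format and column_map", call. = FALSE)
  }
  ev <- ev[keep, , drop = FALSE]
  ev <- sort_events(ev)
  attr(ev, "load_report") <- tibble::tibble(
    rows_read = rows_read, rows_kept = nrow(ev), rows_dropped = dropped)
  ev
}

#' Sort events into canonical order
#'
#' Stable sort by `(hcw_id, patient_id, timestamp)`; events with identical
#' timestamps keep their input order (their mutual gap is 0 s). Duplicate
#' rows are kept: repeated identical actions are legitimate audit entries.
#'
#' @param events Tibble with at least `hcw_id`, `patient_id`, `timestamp`.
#' @return The same tibble, reordered.
#' @export
sort_events <- function(events) {
  ord <- order(events$hcw_id, events$patient_id, events$timestamp,
               method = "radix")
  events[ord, , drop = FALSE]
}

is_sorted_events <- function(events) {
  if (nrow(events) < 2) return(TRUE)
  ord <- order(events$hcw_id, events$patient_id, events$timestamp,
               method = "radix")
  !is.unsorted(ord)
}

#' Read HCW metadata (specialty and role)
#'
#' @param path CSV with columns `hcw_id`, `specialty`, `role`. Any role
#'   outside [hcw_roles()] is recoded to `"unknown"`; duplicated `hcw_id`
#'   rows are an error (each HCW maps to at most one specialty/role).
#' @return Tibble with character columns `hcw_id`, `specialty`, `role`.
#' @export
read_hcw_meta <- function(path) {
  m <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  req <- c("hcw_id", "specialty", "role")
  if (!all(req %in% names(m))) {
    stop("hcw metadata needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(m$hcw_id)) {
    stop("duplicated hcw_id in metadata; each HCW maps to one specialty/role",
         call. = FALSE)
  }
  m$role[!(m$role %in% hcw_roles())] <- "unknown"
  tibble::as_tibble(m[req])
}

#' The eight HCW role categories
#'
#' Care-team roles used to aggregate specialty-level collaboration networks:
#' neonatologists, fellows, frontline providers (nurse practitioners,
#' physician assistants, residents), nurses, respiratory therapists,
#' consultants, ancillary staff, and support staff.
#'
#' @return Character vector of the eight role labels.
#' @export
hcw_roles <- function() {
  c("neonatologist", "fellow", "frontline provider", "nurse",
    "respiratory therapist", "consultant", "ancillary staff", "support staff")
}

#' Read patient visit metadata
#'
#' @param path CSV with columns `patient_id`, `admission`, `discharge`
#'   (timestamps parseable by `timestamp_format`).
#' @param timestamp_format,tz As in [read_events()].
#' @return Tibble `patient_id`, `admission`, `discharge` (`POSIXct`);
#'   rows with `admission >= discharge` are an error.
#' @export
read_visits <- function(path, timestamp_format = "%Y-%m-%d %H:%M:%S",
                        tz = "UTC") {
  v <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  req <- c("patient_id", "admission", "discharge")
  if (!all(req %in% names(v))) {
    stop("visit metadata needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    patient_id = v$patient_id,
    admission = as.POSIXct(v$admission, format = timestamp_format, tz = tz),
    discharge = as.POSIXct(v$discharge, format = timestamp_format, tz = tz))
  if (anyNA(out$admission) || anyNA(out$discharge)) {
    stop("unparseable admission/discharge timestamps", call. = FALSE)
  }
  if (any(out$admission >= out$discharge)) {
    stop("admission must precede discharge for every visit", call. = FALSE)
  }
  out
}

#' Write a tabular artifact as delimited text
#'
#' Writes any of the pipeline's tabular outputs (events, intervals, sessions,
#' intensity records, ...) as CSV with a header. `POSIXct` columns are
#' formatted at second resolution so that string/integer fields round-trip
#' bit-identically through the corresponding reader.
#'
#' @param records A data frame; may have zero rows (header-only file).
#' @param path Output path.
#' @param timestamp_format Format used for `POSIXct` columns.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, timestamp_format = "%m/%d/%Y %H:%M:%S") {
  if (is.null(records)) stop("records must be non-null", call. = FALSE)
  records <- as.data.frame(records)
  for (j in seq_along(records)) {
    if (inherits(records[[j]], "POSIXct")) {
      records[[j]] <- format(records[[j]], timestamp_format)
    }
  }
  tryCatch(
    readr::write_csv(records, path, progress = FALSE),
    error = function(e) stop("cannot write to ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  invisible(path)
}
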