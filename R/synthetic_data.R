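#' Configuration for the synthetic audit-log generator
#'
#' Encodes the statistical structure of a NICU-like audit log at desk
#' scale: multiple HCWs per patient; bursty per-HCW event streams whose
#' inter-event gaps live on two well-separated timescales (seconds within a
#' task, tens of minutes between tasks); planted teams whose members act on
#' shared patients in overlapping time windows; weekday/weekend activity
#' asymmetry; and day-resolution admission/discharge spans per patient
#' (admissions and discharges fall on midnight boundaries, mirroring logs
#' that carry admission and discharge dates).
#'
#' @param n_hcws,n_patients,n_days Cohort sizes (defaults 24 HCWs, 10
#'   patients, 14 days).
#' @param start_date First study day (a `Date`; default a Monday).
#' @param within_gap_mean Mean within-burst inter-event gap, seconds
#'   (default 30).
#' @param between_gap_mean Mean gap between successive bursts of one HCW on
#'   one patient, seconds (default 14400: about six touches per patient per
#'   day, so coordinated team activity — not coincidental overlap —
#'   dominates the concurrency signal).
#' @param events_per_burst_mean Mean events per burst (default 5; every
#'   burst has at least 1 event).
#' @param weekday_rate,weekend_rate Activity multipliers by day type
#'   (defaults 1 and 0.25: weekend bursts and team anchors are thinned to a
#'   quarter of the weekday rate).
#' @param mean_stay_days Mean hospital stay, days (default 6; minimum 2 so
#'   every patient has full admission and discharge windows).
#' @param planted_teams List of `list(members = <hcw ids>, propensity =
#'   <0..1>)`; with probability `propensity` a team member joins each team
#'   anchor on a shared patient with an overlapping burst. Default: three
#'   teams of three with propensity 0.9.
#' @param patients_per_team Shared patients assigned to each planted team
#'   (default 3).
#' @param anchor_rate Expected team anchors per (team, shared patient,
#'   weekday) (default 3).
#' @param hcws_per_patient Care-team size sampled per patient (default 3;
#'   planted team members are added on top for shared patients).
#' @param shift_start_hour,shift_hours Daily activity window (default the
#'   full 24 h day: a NICU is staffed around the clock).
#' @param n_actions Action vocabulary size (default 40).
#' @param n_templates Number of action templates; each burst draws all its
#'   actions from one template, so intervals from the same template share a
#'   composition profile (default 6). Template cores are disjoint action
#'   subsets when the vocabulary is large enough (distinct task types).
#' @param actions_per_template Distinct actions a template concentrates on
#'   (default 6).
#' @param seed Integer seed; mandatory — all randomness flows from it.
#' @return A validated `"sim_config"` list.
#' @export
sim_config <- function(n_hcws = 24, n_patients = 10, n_days = 14,
                       start_date = as.Date("2024-03-04"),
                       within_gap_mean = 30, between_gap_mean = 14400,
                       events_per_burst_mean = 5,
                       weekday_rate = 1, weekend_rate = 0.25,
                       mean_stay_days = 6,
                       planted_teams = NULL, patients_per_team = 3,
                       anchor_rate = 3, hcws_per_patient = 3,
                       shift_start_hour = 0, shift_hours = 24,
                       n_actions = 40, n_templates = 6,
                       actions_per_template = 6, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  hcw_ids <- sprintf("h%03d", seq_len(n_hcws))
  if (is.null(planted_teams)) {
    planted_teams <- list(
      list(members = hcw_ids[1:3], propensity = 0.9),
      list(members = hcw_ids[4:6], propensity = 0.9),
      list(members = hcw_ids[7:9], propensity = 0.9))
  }
  cfg <- list(n_hcws = n_hcws, n_patients = n_patients, n_days = n_days,
              start_date = as.Date(start_date),
              within_gap_mean = within_gap_mean,
              between_gap_mean = between_gap_mean,
              events_per_burst_mean = events_per_burst_mean,
              weekday_rate = weekday_rate, weekend_rate = weekend_rate,
              mean_stay_days = mean_stay_days,
              planted_teams = planted_teams,
              patients_per_team = patients_per_team,
              anchor_rate = anchor_rate,
              hcws_per_patient = hcws_per_patient,
              shift_start_hour = shift_start_hour,
              shift_hours = shift_hours,
              n_actions = n_actions, n_templates = n_templates,
              actions_per_template = actions_per_template,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_hcws >= 2, n_patients >= 1, n_days >= 2,
              within_gap_mean > 0, between_gap_mean > within_gap_mean,
              events_per_burst_mean >= 1,
              weekday_rate > 0, weekend_rate > 0,
              mean_stay_days >= 2, anchor_rate > 0,
              hcws_per_patient >= 2, hcws_per_patient <= n_hcws,
              n_actions >= actions_per_template, n_templates >= 1,
              patients_per_team >= 1, patients_per_team <= n_patients)
  })
  hcw_ids <- sprintf("h%03d", seq_len(cfg$n_hcws))
  for (tm in cfg$planted_teams) {
    if (length(tm$members) > cfg$n_hcws ||
        !all(tm$members %in% hcw_ids)) {
      stop("planted team members must be among the generated HCW ids (",
           hcw_ids[1], "..", hcw_ids[cfg$n_hcws], ")", call. = FALSE)
    }
    if (tm$propensity < 0 || tm$propensity > 1) {
      stop("team propensity must be in [0, 1]", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Generate a synthetic audit log with known ground truth
#'
#' Simulates the event stream, HCW metadata, and visit table the pipeline
#' consumes, plus the ground truth needed to score recovery. Each patient
#' gets a care team; each (HCW, patient, stay-day) emits bursts whose start
#' times are spaced by exponential gaps at the between-task scale (thinned
#' on weekends), and whose events are spaced at the within-task scale. For
#' every planted team, anchors on shared patients draw team members into
#' overlapping bursts with the team's propensity; all bursts of one anchor
#' share one action template. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `events` (sorted tibble: `hcw_id`, `patient_id`,
#'   `action_id`, `timestamp`), `hcw_meta`, `visits`, and `truth` (list:
#'   `bursts` tibble with per-burst template/team/anchor flags, `teams`,
#'   `templates`, `config`).
#' @export
generate_audit_log <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(config$seed)
  cfg <- config

  hcw_ids <- sprintf("h%03d", seq_len(cfg$n_hcws))
  pat_ids <- sprintf("p%03d", seq_len(cfg$n_patients))
  roles <- sample(hcw_roles(), cfg$n_hcws, replace = TRUE,
                  prob = c(0.08, 0.05, 0.15, 0.35, 0.10, 0.10, 0.12, 0.05))
  hcw_meta <- tibble::tibble(
    hcw_id = hcw_ids, role = roles,
    specialty = paste0(roles, "-", sample(1:2, cfg$n_hcws, replace = TRUE)))
  hcw_meta <- hcw_meta[, c("hcw_id", "specialty", "role")]

  t0_study <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")
  stay <- pmin(2 + stats::rpois(cfg$n_patients, cfg$mean_stay_days - 2),
               cfg$n_days)
  adm_day <- vapply(stay, function(s) {
    sample.int(cfg$n_days - s + 1, 1) - 1L
  }, integer(1))
  visits <- tibble::tibble(
    patient_id = pat_ids,
    admission = t0_study + adm_day * 86400,
    discharge = t0_study + (adm_day + stay) * 86400)

  # care teams: random base team per patient, planted teams added en bloc
  assign_list <- lapply(seq_len(cfg$n_patients), function(i) {
    sample(hcw_ids, cfg$hcws_per_patient)
  })
  team_patients <- vector("list", length(cfg$planted_teams))
  for (ti in seq_along(cfg$planted_teams)) {
    ps <- sample.int(cfg$n_patients, cfg$patients_per_team)
    team_patients[[ti]] <- ps
    for (p in ps) {
      assign_list[[p]] <- union(assign_list[[p]],
                                cfg$planted_teams[[ti]]$members)
    }
  }

  # action templates: each concentrates most mass on its own action subset;
  # cores are disjoint when the vocabulary allows (distinct task types)
  acts <- sprintf("ACTION %02d", seq_len(cfg$n_actions))
  need <- cfg$n_templates * cfg$actions_per_template
  core_pool <- if (cfg$n_actions >= need) {
    split(sample(acts, need),
          rep(seq_len(cfg$n_templates), each = cfg$actions_per_template))
  } else {
    lapply(seq_len(cfg$n_templates),
           function(i) sample(acts, cfg$actions_per_template))
  }
  templates <- lapply(seq_len(cfg$n_templates), function(ti) {
    core <- core_pool[[ti]]
    p <- stats::setNames(rep(0.02 / cfg$n_actions, cfg$n_actions), acts)
    p[core] <- p[core] + 0.98 / cfg$actions_per_template
    p / sum(p)
  })

  day_mult <- function(dayn) {
    wd <- format(t0_study + dayn * 86400, "%u", tz = "UTC")
    ifelse(wd %in% c("6", "7"), cfg$weekend_rate, cfg$weekday_rate)
  }
  shift0 <- cfg$shift_start_hour * 3600
  shift_len <- cfg$shift_hours * 3600

  bursts <- list()
  bi <- 0L
  add_burst <- function(hcw, pat, t0, tmpl, team, anchored) {
    bi <<- bi + 1L
    bursts[[bi]] <<- list(hcw_id = hcw, patient_id = pat, t0 = t0,
                          template = tmpl, team = team, anchored = anchored)
  }

  # ordinary (individual) bursts
  for (p in seq_len(cfg$n_patients)) {
    days <- adm_day[p]:(adm_day[p] + stay[p] - 1)
    for (h in assign_list[[p]]) {
      for (d in days) {
        rate <- day_mult(d) / cfg$between_gap_mean
        k <- max(10, ceiling(shift_len * rate * 3))
        offs <- cumsum(stats::rexp(k, rate))
        offs <- offs[offs < shift_len]
        for (o in offs) {
          add_burst(h, pat_ids[p], d * 86400 + shift0 + o,
                    sample.int(cfg$n_templates, 1), NA_integer_, FALSE)
        }
      }
    }
  }

  # planted team anchors: members join with the team's propensity
  for (ti in seq_along(cfg$planted_teams)) {
    tm <- cfg$planted_teams[[ti]]
    for (p in team_patients[[ti]]) {
      days <- adm_day[p]:(adm_day[p] + stay[p] - 1)
      for (d in days) {
        n_anchor <- stats::rpois(1, cfg$anchor_rate * day_mult(d))
        if (n_anchor == 0) next
        for (a in seq_len(n_anchor)) {
          at <- d * 86400 + shift0 + stats::runif(1, 0, shift_len)
          tmpl <- sample.int(cfg$n_templates, 1)
          join <- stats::runif(length(tm$members)) < tm$propensity
          for (h in tm$members[join]) {
            add_burst(h, pat_ids[p], at + stats::runif(1, 0, 20),
                      tmpl, ti, TRUE)
          }
        }
      }
    }
  }

  if (bi == 0L) stop("configuration produced no activity", call. = FALSE)
  bursts <- dplyr::bind_rows(bursts[seq_len(bi)])
  bursts$burst_id <- seq_len(nrow(bursts))

  # events: within-burst gaps at the short timescale, one template per burst
  n_ev <- 1L + stats::rpois(nrow(bursts), cfg$events_per_burst_mean - 1)
  idx <- rep.int(seq_len(nrow(bursts)), n_ev)
  gaps <- stats::rexp(length(idx), 1 / cfg$within_gap_mean)
  first <- !duplicated(idx)
  gaps[first] <- 0
  cs <- cumsum(gaps)
  within <- cs - cs[first][idx]
  ev_time <- round(bursts$t0[idx] + within)
  tmpl_of_ev <- bursts$template[idx]
  action <- character(length(idx))
  for (ti in seq_len(cfg$n_templates)) {
    sel <- tmpl_of_ev == ti
    if (any(sel)) {
      action[sel] <- sample(acts, sum(sel), replace = TRUE,
                            prob = templates[[ti]])
    }
  }
  events <- tibble::tibble(
    hcw_id = bursts$hcw_id[idx],
    patient_id = bursts$patient_id[idx],
    action_id = action,
    timestamp = t0_study + ev_time,
    burst_id = bursts$burst_id[idx])
  events <- events[order(events$hcw_id, events$patient_id, events$timestamp,
                         events$burst_id), , drop = FALSE]
  bursts$n_events <- n_ev
  bursts$t0 <- t0_study + bursts$t0

  list(events = events[, c("hcw_id", "patient_id", "action_id", "timestamp")],
       hcw_meta = hcw_meta, visits = visits,
       truth = list(bursts = bursts, teams = cfg$planted_teams,
                    team_patients = lapply(team_patients,
                                           function(p) pat_ids[p]),
                    templates = templates, event_burst = events$burst_id,
                    config = cfg))
}

#' All planted collaborating HCW pairs of a ground truth
#'
#' @param truth The `truth` element of [generate_audit_log()] output.
#' @return Tibble `hcw_a`, `hcw_b` (sorted within pair, unique).
#' @export
planted_pairs <- function(truth) {
  out <- lapply(truth$teams, function(tm) {
    if (length(tm$members) < 2) return(NULL)
    cp <- utils::combn(sort(tm$members), 2)
    tibble::tibble(hcw_a = cp[1, ], hcw_b = cp[2, ])
  })
  dplyr::distinct(dplyr::bind_rows(out))
}

#' Score pipeline recovery against the generator's ground truth
#'
#' Compares pipeline outputs with what the generator planted: (a) whether
#' the estimated gap cutoff separates the two configured gap scales, (b)
#' precision of the top-weighted collaboration edges against planted team
#' pairs, (c) the weekday/weekend ratio of mean hourly concurrency against
#' the configured rate ratio, and (d) the single-cluster session fraction
#' expected under template-homogeneous sessions. Components not supplied
#' are skipped.
#'
#' @param truth The `truth` element of [generate_audit_log()] output.
#' @param cutoff Estimated gap cutoff (seconds), or `NULL`.
#' @param graph Collaboration graph from [build_graph()], or `NULL`.
#' @param pattern_weekday,pattern_weekend `"temporal_pattern"` objects, or
#'   `NULL`.
#' @param complexity Output of [session_complexity()], or `NULL`.
#' @return A list of recovery measures (see details above); `NULL` entries
#'   for skipped components.
#' @export
score_recovery <- function(truth, cutoff = NULL, graph = NULL,
                           pattern_weekday = NULL, pattern_weekend = NULL,
                           complexity = NULL) {
  cfg <- truth$config
  out <- list()
  if (!is.null(cutoff)) {
    out$cutoff <- as.numeric(cutoff)
    out$cutoff_between_scales <- cutoff > cfg$within_gap_mean &&
      cutoff < cfg$between_gap_mean
  }
  if (!is.null(graph)) {
    pp <- planted_pairs(truth)
    el <- igraph::as_data_frame(graph, what = "edges")
    el$a <- pmin(el$from, el$to)
    el$b <- pmax(el$from, el$to)
    el <- el[order(-el$weight, el$a, el$b), , drop = FALSE]
    top <- utils::head(el, nrow(pp))
    hit <- paste(top$a, top$b) %in% paste(pp$hcw_a, pp$hcw_b)
    out$edge_precision <- if (nrow(pp) > 0) mean(hit) else NA_real_
    out$n_planted_pairs <- nrow(pp)
  }
  if (!is.null(pattern_weekday) && !is.null(pattern_weekend)) {
    mw <- mean(pattern_weekday$mean_counts)
    me <- mean(pattern_weekend$mean_counts)
    out$weekday_weekend_ratio <- if (me > 0) mw / me else Inf
    out$configured_ratio <- cfg$weekday_rate / cfg$weekend_rate
  }
  if (!is.null(complexity)) {
    d <- complexity$distribution
    out$single_cluster_fraction <-
      sum(d$fraction[d$n_clusters_class == "1"])
  }
  out
}
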