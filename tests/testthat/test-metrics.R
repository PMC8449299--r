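# labeled intervals for one HCW-day: durations in minutes, flags
one_day_intervals <- function(durations_min, concurrent) {
  n <- length(durations_min)
  start <- 3600 * 8 + cumsum(c(0, utils::head(durations_min, -1) * 60 + 600))
  iv <- int_tbl(rep("A", n), "1", start, start + durations_min * 60)
  iv$concurrent <- concurrent
  iv$session_id <- ifelse(concurrent, "s", NA_character_)
  iv
}

test_that("daily intensity proportions follow the labeled intervals", {
  iv <- one_day_intervals(c(10, 10, 10, 10), c(TRUE, FALSE, FALSE, FALSE))
  rec <- compute_intensity(iv, flag_workdays(iv, 15))
  expect_equal(rec$prop_intervals, 0.25)
  expect_equal(rec$prop_time, 0.25)
  expect_equal(rec$ehr_time, 40)
  expect_equal(rec$n_actions, 4)

  iv <- one_day_intervals(c(10, 20), c(TRUE, TRUE))
  rec <- compute_intensity(iv, flag_workdays(iv, 15))
  expect_equal(rec$prop_intervals, 1)
  expect_equal(rec$prop_time, 1)

  iv <- one_day_intervals(c(10, 20), c(FALSE, FALSE))
  rec <- compute_intensity(iv, flag_workdays(iv, 15))
  expect_equal(rec$prop_intervals, 0)
  expect_equal(rec$prop_time, 0)
})

test_that("inactive days are excluded and ehr_time reconciles with workdays", {
  withr::local_seed(31)
  ev <- random_stream(1500, n_hcws = 6, n_patients = 4,
                      within = 30, between = 3000, p_break = 0.15)
  pipe <- collaboration_pipeline(ev, cutoff = 120, workday_cutoff = 2)
  rec <- compute_intensity(pipe$intervals, pipe$workdays)
  active <- pipe$workdays[pipe$workdays$active, ]
  expect_equal(nrow(rec), nrow(active))
  j <- dplyr::inner_join(rec, active, by = c("hcw_id", "date"),
                         suffix = c("", ".wd"))
  expect_equal(j$ehr_time, j$ehr_time.wd)
  expect_true(all(rec$n_concurrent <= rec$n_intervals))
  expect_true(all(rec$concurrent_time <= rec$ehr_time + 1e-9))
})

test_that("a corrupted workday table is a fatal consistency error", {
  iv <- one_day_intervals(c(10, 10), c(TRUE, FALSE))
  wd <- flag_workdays(iv, 15)
  wd$ehr_time <- wd$ehr_time + 5
  expect_error(compute_intensity(iv, wd), "inconsistent")
})

test_that("intensity is invariant to relabeling HCW and patient ids", {
  withr::local_seed(32)
  ev <- random_stream(600, n_hcws = 4, n_patients = 3)
  pipe <- collaboration_pipeline(ev, cutoff = 120, workday_cutoff = 1)
  rec1 <- compute_intensity(pipe$intervals, pipe$workdays)
  ev2 <- ev
  ev2$hcw_id <- paste0("X", ev2$hcw_id)
  ev2$patient_id <- paste0("Y", ev2$patient_id)
  ev2 <- sort_events(ev2)
  pipe2 <- collaboration_pipeline(ev2, cutoff = 120, workday_cutoff = 1)
  rec2 <- compute_intensity(pipe2$intervals, pipe2$workdays)
  rec2$hcw_id <- sub("^X", "", rec2$hcw_id)
  cols <- c("n_intervals", "n_concurrent", "ehr_time", "prop_intervals",
            "prop_time")
  expect_equal(as.data.frame(dplyr::arrange(rec2[c("hcw_id", "date", cols)],
                                            hcw_id, date)),
               as.data.frame(dplyr::arrange(rec1[c("hcw_id", "date", cols)],
                                            hcw_id, date)))
})

fake_records <- function(hcws, specialty, prop_time, n_days = 5, sd = 0) {
  withr::local_seed(99)
  recs <- lapply(seq_along(hcws), function(i) {
    tibble::tibble(
      hcw_id = hcws[i], date = as.Date("2024-01-01") + seq_len(n_days),
      n_intervals = 10L, n_concurrent = 3L,
      ehr_time = 60, concurrent_time = 60 * prop_time[i],
      n_actions = 50,
      prop_intervals = 0.3,
      prop_time = pmin(1, pmax(0, prop_time[i] + stats::rnorm(n_days, 0, sd))))
  })
  dplyr::bind_rows(recs)
}

test_that("specialty summaries average per-HCW means, not HCW-days", {
  meta <- tibble::tibble(hcw_id = c("a", "b"), specialty = "s1",
                         role = "nurse")
  # HCW a has many more days; two-stage averaging keeps the mean at 0.5
  rec <- dplyr::bind_rows(fake_records("a", "s1", 0.4, n_days = 20),
                          fake_records("b", "s1", 0.6, n_days = 2))
  sm <- summarize_by_specialty(rec, meta)
  expect_equal(sm$prop_time, 0.5)
  expect_equal(sm$n_hcws, 2L)
  expect_true(sm$prop_time_lo <= sm$prop_time &&
                sm$prop_time <= sm$prop_time_hi)
})

test_that("top_k ranks by mean EHR time; single-HCW specialties lack CIs", {
  meta <- tibble::tibble(hcw_id = c("a", "b", "c"),
                         specialty = c("s1", "s1", "s2"), role = "nurse")
  rec <- dplyr::bind_rows(fake_records(c("a", "b"), "s1", c(0.2, 0.4)),
                          fake_records("c", "s2", 0.5))
  rec$ehr_time[rec$hcw_id == "c"] <- 200
  sm <- summarize_by_specialty(rec, meta, top_k = 1)
  expect_equal(sm$specialty, "s2")
  expect_true(is.na(sm$ehr_time_lo))
})

test_that("identical specialty distributions give F near 0, p near 1", {
  meta <- tibble::tibble(hcw_id = letters[1:4],
                         specialty = c("s1", "s1", "s2", "s2"),
                         role = "nurse")
  rec <- fake_records(letters[1:4], NA, c(0.3, 0.5, 0.3, 0.5))
  cmp <- compare_specialties(rec, meta)
  f <- cmp$anova$f[cmp$anova$metric == "prop_time"]
  p <- cmp$anova$p_value[cmp$anova$metric == "prop_time"]
  expect_lt(abs(f), 1e-20)
  expect_gt(p, 0.99)
})

test_that("a planted large specialty gap is detected at p < .001", {
  meta <- tibble::tibble(hcw_id = sprintf("h%02d", 1:60),
                         specialty = rep(c("s1", "s2"), each = 30),
                         role = "nurse")
  rec <- fake_records(meta$hcw_id, NA,
                      rep(c(0.1, 0.7), each = 30), n_days = 5, sd = 0.05)
  cmp <- compare_specialties(rec, meta)
  expect_lt(cmp$anova$p_value[cmp$anova$metric == "prop_time"], 0.001)
  expect_true(cmp$anova$significant[cmp$anova$metric == "prop_time"])
})

test_that("perfectly monotone EHR vs concurrent time gives Spearman rho 1", {
  meta <- tibble::tibble(hcw_id = "a", specialty = "s1", role = "nurse")
  rec <- tibble::tibble(hcw_id = "a",
                        date = as.Date("2024-01-01") + 1:10,
                        n_intervals = 5L, n_concurrent = 2L,
                        ehr_time = seq(10, 100, 10),
                        concurrent_time = seq(5, 50, 5)^1.3,
                        n_actions = 10, prop_intervals = 0.4, prop_time = 0.5)
  meta2 <- tibble::tibble(hcw_id = c("a", "b", "c", "d", "e"),
                          specialty = c("s1", "s2", "s2", "s3", "s3"),
                          role = "nurse")
  rec2 <- dplyr::bind_rows(
    rec, fake_records(c("b", "c", "d", "e"), NA, c(0.2, 0.3, 0.4, 0.5)))
  cmp <- compare_specialties(rec2, meta2)
  expect_equal(cmp$spearman$rho[cmp$spearman$specialty == "s1"], 1)
})
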