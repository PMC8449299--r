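test_that("the worked two-HCW example sessionizes at a 2-minute cutoff", {
  ev <- example_events()
  iv <- build_intervals(ev, 120, keep_actions = TRUE)
  a <- iv[iv$hcw_id == "A", ]
  # gaps 35, 203, 90, 99, 51 s: the 203 s gap splits the run in two
  expect_equal(nrow(a), 2)
  expect_equal(a$n_events, c(2L, 4L))
  expect_equal(a$duration, c(35, 240))
  expect_equal(format(a$start[2], "%H:%M:%S"), "02:18:23")
  b <- iv[iv$hcw_id == "B", ]
  # all of B's gaps (104, 90, 106, 66, 114 s) stay under the cutoff
  expect_equal(nrow(b), 1)
  expect_equal(b$duration, 480)
  expect_equal(b$n_events, 6L)
  expect_equal(lengths(iv$actions), iv$n_events)
})

test_that("single events become zero-duration intervals; boundary gaps stay", {
  iv <- build_intervals(ev_tbl("A", "1", 0), 120)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$duration, 0)
  # a gap exactly equal to the cutoff does not split
  iv2 <- build_intervals(ev_tbl("A", "1", c(0, 120, 241)), 120)
  expect_equal(iv2$n_events, c(2L, 1L))
})

test_that("unsorted input is rejected", {
  ev <- tibble::tibble(hcw_id = c("B", "A"), patient_id = "1",
                       action_id = "X", timestamp = T0 + c(0, 10))
  expect_error(build_intervals(ev, 60), "sorted")
  expect_error(estimate_cutoff(ev), "sorted")
})

test_that("build_intervals matches the naive linear-scan oracle", {
  withr::local_seed(41)
  for (rep in 1:25) {
    ev <- random_stream(sample(20:400, 1))
    cutoff <- sample(c(5, 30, 120, 600), 1)
    ids <- event_intervals(ev, cutoff)$interval_id
    expect_equal(ids, oracle_interval_ids(ev, cutoff))
  }
})

test_that("events partition into intervals and counts are monotone in cutoff", {
  withr::local_seed(42)
  ev <- random_stream(800)
  cutoffs <- c(5, 20, 60, 180, 600, 1800)
  counts <- numeric(0)
  durations <- numeric(0)
  for (co in cutoffs) {
    iv <- build_intervals(ev, co)
    expect_equal(sum(iv$n_events), nrow(ev))   # partition property
    # within-group non-overlap of consecutive intervals
    same <- iv$hcw_id[-1] == iv$hcw_id[-nrow(iv)] &
      iv$patient_id[-1] == iv$patient_id[-nrow(iv)]
    expect_true(all(as.numeric(iv$start[-1]) -
                      as.numeric(iv$stop[-nrow(iv)]) > co | !same))
    counts <- c(counts, nrow(iv))
    durations <- c(durations, sum(iv$duration))
  }
  expect_true(all(diff(counts) <= 0))
  expect_true(all(diff(durations) >= 0))
})

test_that("discrete curvature of a parabola is 2 at the vertex", {
  x <- seq(-1, 1, by = 0.1)
  k <- discrete_curvature(x, x^2)
  expect_equal(k[x == 0], 2, tolerance = 1e-10)
})

test_that("knee_point finds the breakpoint of a piecewise-linear curve", {
  x <- seq(0, 10, by = 0.25)
  y <- ifelse(x <= 2, 20 - 10 * x, -0.1 * (x - 2))
  expect_equal(as.numeric(knee_point(x, y, smoothing = 1)), 2)
  # independent check: discrete curvature peaks at the breakpoint (the
  # finite-difference stencil can land one grid step to either side)
  expect_lte(abs(x[which.max(abs(discrete_curvature(x, y)))] - 2), 0.25)
})

test_that("knee_point rejects lines, flat curves, and tiny inputs", {
  x <- seq(0, 10, by = 0.5)
  expect_error(knee_point(x, 5 - x), "no knee")
  expect_error(knee_point(x, rep(3, length(x))), "no knee")
  expect_error(knee_point(1:4, c(4, 3, 2, 1)), "at least 5")
})

test_that("knee_point is invariant to affine rescaling of both axes", {
  withr::local_seed(7)
  x <- seq(1, 50)
  y <- 100 * exp(-x / 5) + 2
  k1 <- as.numeric(knee_point(x, y))
  k2 <- as.numeric(knee_point(3 * x + 11, -2 * y + 5))
  expect_equal(3 * k1 + 11, k2)
})

test_that("knee ties resolve to the smallest candidate", {
  # symmetric double knee: difference curve attains its max twice
  x <- 0:10
  y <- c(10, 10, 10, 5, 0, 0, 0, -5, -10, -10, -10)
  k <- knee_point(x, y, smoothing = 1)
  d <- attr(k, "curve")$difference
  expect_gte(sum(d == max(d)), 1)
  expect_equal(as.numeric(k), x[which(d == max(d))[1]])
})

test_that("estimate_cutoff lands between two planted gap scales", {
  withr::local_seed(11)
  # two gap values only: 5 s within, 500 s between
  t <- cumsum(rep(c(5, 5, 5, 500), 50))
  ev <- ev_tbl("A", "1", t)
  co <- estimate_cutoff(ev, candidate_cutoffs = seq(10, 1800, by = 10),
                        smoothing = 1)
  expect_gte(as.numeric(co), 5)
  expect_lte(as.numeric(co), 500)

  # exponential mixture: within ~Exp(30), between ~Exp(1200)
  hcw <- rep(sprintf("h%03d", 1:50), each = 100)
  gaps <- as.vector(replicate(50, {
    g <- stats::rexp(99, 1 / 30)
    g[seq(5, 99, by = 5)] <- stats::rexp(length(seq(5, 99, by = 5)), 1 / 1200)
    c(0, g)
  }))
  t <- as.vector(vapply(split(gaps, hcw), cumsum, numeric(100)))
  ev <- ev_tbl(hcw, "1", round(t))
  co <- as.numeric(estimate_cutoff(ev))
  expect_gte(co, 30)
  expect_lte(co, 1200)
})

test_that("estimate_cutoff's curve equals interval counts from build_intervals", {
  withr::local_seed(12)
  ev <- random_stream(300)
  cands <- seq(10, 1810, by = 100)
  co <- estimate_cutoff(ev, candidate_cutoffs = cands)
  curve <- attr(co, "curve")
  direct <- vapply(cands, function(c) nrow(build_intervals(ev, c)), numeric(1))
  expect_equal(curve$y, direct)
})

test_that("a flat interval-count curve yields a no-knee error", {
  ev <- ev_tbl("A", "1", seq(0, 45, by = 5))  # all gaps 5 s
  expect_error(estimate_cutoff(ev, candidate_cutoffs = seq(10, 1800, 10)),
               "no knee")
})

test_that("workday flags respect the cutoff and split at midnight", {
  iv <- int_tbl("A", "1", 3600, 3600 + 1200)        # one 20-min interval
  wd <- flag_workdays(iv, 15)
  expect_true(wd$active)
  iv <- int_tbl(rep("A", 3), "1", c(0, 1000, 2000) * 10,
                c(0, 1000, 2000) * 10 + 240)        # three 4-min intervals
  wd <- flag_workdays(iv, 15)
  expect_equal(nrow(wd), 1)
  expect_equal(wd$ehr_time, 12)
  expect_false(wd$active)
  # 23:50 to 00:10 contributes 10 minutes to each side of midnight
  iv <- int_tbl("A", "1", 86400 - 600, 86400 + 600)
  wd <- flag_workdays(iv, 15)
  expect_equal(nrow(wd), 2)
  expect_equal(wd$ehr_time, c(10, 10))
  expect_false(any(wd$active))
})
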