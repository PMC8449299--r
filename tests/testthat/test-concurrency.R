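test_that("overlap requires same patient, different HCW, positive width", {
  iv <- int_tbl(c("A", "B"), "1", c(0, 10), c(10, 20))
  expect_equal(nrow(find_overlap_pairs(iv)), 0)   # touching endpoints
  iv <- int_tbl(c("A", "B"), "1", c(0, 5), c(10, 20))
  p <- find_overlap_pairs(iv)
  expect_equal(nrow(p), 1)
  expect_equal(p$overlap, 5)
  iv <- int_tbl(c("A", "B"), c("1", "2"), c(0, 0), c(10, 10))
  expect_equal(nrow(find_overlap_pairs(iv)), 0)   # cross-patient
  iv <- int_tbl(c("A", "A"), "1", c(0, 5), c(10, 20))
  expect_equal(nrow(find_overlap_pairs(iv)), 0)   # same HCW
})

test_that("sessions are connected components, transitively linked", {
  # chain: A overlaps B, B overlaps C, A and C never overlap directly
  iv <- int_tbl(c("A", "B", "C"), "1", c(0, 8, 14), c(10, 15, 20))
  s <- assemble_sessions(find_overlap_pairs(iv), iv)
  expect_equal(dplyr::n_distinct(s$session_id), 1)
  expect_equal(sort(s$hcw_id), c("A", "B", "C"))
  # two disjoint overlapping pairs on one patient form two sessions
  iv <- int_tbl(c("A", "B", "A", "B"), "1",
                c(0, 4, 100, 105), c(5, 8, 110, 120))
  s <- assemble_sessions(find_overlap_pairs(iv), iv)
  expect_equal(dplyr::n_distinct(s$session_id), 2)
  # no pairs: no sessions, everything individual
  iv <- int_tbl(c("A", "B"), "1", c(0, 50), c(10, 60))
  s <- assemble_sessions(find_overlap_pairs(iv), iv)
  expect_equal(nrow(s), 0)
  lab <- label_intervals(iv, s)
  expect_false(any(lab$concurrent))
})

test_that("the clique rule splits components without a common instant", {
  iv <- int_tbl(c("A", "B", "C"), "1", c(0, 8, 14), c(10, 15, 20))
  pr <- find_overlap_pairs(iv)
  comp <- assemble_sessions(pr, iv, rule = "component")
  expect_equal(nrow(comp), 3)
  clq <- assemble_sessions(pr, iv, rule = "clique")
  # A and B share an instant; C's overlap partner is already claimed
  expect_equal(sort(clq$hcw_id), c("A", "B"))
  expect_equal(dplyr::n_distinct(clq$session_id), 1)
})

test_that("labeling partitions intervals and reports counts", {
  iv <- int_tbl(c("A", "B", "C", "D"), c("1", "1", "2", "3"),
                c(0, 5, 0, 0), c(10, 15, 10, 10))
  s <- assemble_sessions(find_overlap_pairs(iv), iv)
  lab <- label_intervals(iv, s)
  expect_equal(sum(lab$concurrent), 2)
  rep <- attr(lab, "label_report")
  expect_equal(rep$n_concurrent, 2)
  expect_equal(rep$n_individual, 2)
  # all mutually overlapping intervals by distinct HCWs: one session
  iv <- int_tbl(c("A", "B", "C"), "1", c(0, 1, 2), c(10, 11, 12))
  s <- assemble_sessions(find_overlap_pairs(iv), iv)
  lab <- label_intervals(iv, s)
  expect_true(all(lab$concurrent))
  expect_equal(dplyr::n_distinct(s$session_id), 1)
})

test_that("sweep-line pair finding equals all-pairs brute force", {
  withr::local_seed(21)
  for (rep in 1:20) {
    n <- sample(5:150, 1)
    start <- round(stats::runif(n, 0, 2000))
    iv <- int_tbl(sprintf("h%d", sample.int(5, n, TRUE)),
                  sprintf("p%d", sample.int(3, n, TRUE)),
                  start, start + round(stats::rexp(n, 1 / 120)))
    got <- dplyr::arrange(
      find_overlap_pairs(iv)[, c("interval_a", "interval_b", "overlap")],
      interval_a, interval_b)
    expect_equal(as.data.frame(got), as.data.frame(oracle_pairs(iv)))
  }
})

test_that("session membership partitions concurrent intervals", {
  withr::local_seed(22)
  n <- 200
  start <- round(stats::runif(n, 0, 5000))
  iv <- int_tbl(sprintf("h%d", sample.int(6, n, TRUE)),
                sprintf("p%d", sample.int(4, n, TRUE)),
                start, start + round(stats::rexp(n, 1 / 150)))
  pr <- find_overlap_pairs(iv)
  s <- assemble_sessions(pr, iv)
  expect_equal(anyDuplicated(s$interval_id), 0)
  expect_setequal(s$interval_id, unique(c(pr$interval_a, pr$interval_b)))
  # every session has >=2 intervals from >=2 HCWs on one patient
  ss <- session_summary(s)
  expect_true(all(ss$n_intervals >= 2))
  expect_true(all(ss$n_hcws >= 2))
  # brute-force transitive closure groups the same intervals together
  comp <- oracle_components(pr, as.character(sort(unique(s$interval_id))))
  got_grp <- split(as.character(s$interval_id), s$session_id)
  want_grp <- split(names(comp), comp)
  norm <- function(g) sort(vapply(g, function(x) paste(sort(x), collapse = ","),
                                  character(1)), method = "radix")
  expect_equal(unname(norm(got_grp)), unname(norm(want_grp)))
})

test_that("an interval overlapping nothing leaves existing sessions alone", {
  iv <- int_tbl(c("A", "B"), "1", c(0, 5), c(10, 15))
  s1 <- assemble_sessions(find_overlap_pairs(iv), iv)
  iv2 <- rbind(iv, int_tbl("C", "1", 100, 110))
  iv2$interval_id <- seq_len(3)
  s2 <- assemble_sessions(find_overlap_pairs(iv2), iv2)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
})

test_that("intermediate matrices satisfy their structural invariants", {
  withr::local_seed(23)
  ev <- random_stream(500, n_hcws = 5, n_patients = 3, within = 20,
                      between = 400, p_break = 0.3)
  ev$interval_id <- event_intervals(ev, 120)$interval_id
  iv <- build_intervals(ev, 120)
  s <- assemble_sessions(find_overlap_pairs(iv), iv)
  lab <- label_intervals(iv, s)
  ms <- build_matrices(lab, s, events = ev)
  expect_s3_class(ms, "ehr_matrix_set")
  # every concurrent interval in exactly one session
  expect_true(all(Matrix::rowSums(ms$interval_session) == 1))
  # every session involves >=2 HCWs
  expect_true(all(Matrix::colSums(ms$hcw_session) >= 2))
  # action row sums equal interval event counts
  conc <- lab[lab$concurrent, ]
  expect_equal(unname(Matrix::rowSums(ms$interval_action)),
               as.numeric(conc$n_events))
  # co-session diagonal equals per-HCW session counts
  co <- Matrix::tcrossprod(ms$hcw_session)
  expect_equal(unname(Matrix::diag(co)),
               unname(Matrix::rowSums(ms$hcw_session)))
  # duration-weighted variants carry the interval durations
  expect_equal(unname(Matrix::rowSums(ms$hcw_interval_dur)),
               unname(as.vector(tapply(conc$duration, conc$hcw_id, sum))))
})

test_that("empty session sets produce empty but valid matrices", {
  iv <- int_tbl(c("A", "B"), "1", c(0, 50), c(10, 60))
  s <- assemble_sessions(find_overlap_pairs(iv), iv)
  lab <- label_intervals(iv, s)
  ms <- build_matrices(lab, s)
  expect_equal(dim(ms$interval_session), c(0, 0))
  expect_equal(dim(ms$hcw_session), c(0, 0))
})

test_that("matrix sets round-trip through triplet CSV files", {
  withr::local_seed(24)
  ev <- random_stream(300, n_hcws = 4, n_patients = 2, within = 15,
                      between = 300, p_break = 0.3)
  ev$interval_id <- event_intervals(ev, 90)$interval_id
  iv <- build_intervals(ev, 90)
  s <- assemble_sessions(find_overlap_pairs(iv), iv)
  ms <- build_matrices(label_intervals(iv, s), s, events = ev)
  d <- withr::local_tempdir()
  write_matrix_set(ms, d)
  back <- read_matrix_set(d)
  for (nm in names(ms)) {
    expect_equal(as.matrix(back[[nm]]), as.matrix(ms[[nm]]), label = nm)
  }
})
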