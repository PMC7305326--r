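test_that("build_intervals implements RR(t_i) = t_{i+1} - t_i", {
  bi <- build_intervals(c(0.0, 0.5, 1.1))
  expect_equal(bi$intervals, c(0.5, 0.6))
  expect_equal(bi$times, c(0.0, 0.5))
  expect_true(all(bi$mask))
  expect_length(build_intervals(c(2.0, 2.8))$intervals, 1L)
  expect_error(build_intervals(c(1.0, 0.9)), "index 2")
  expect_error(build_intervals(1.0), "at least 2")
})

test_that("range filter is a closed-interval acceptance and only masks", {
  bi <- build_intervals(cumsum(c(1, 0.25, 0.5, 1.3, 0.3)))
  out <- filter_range(bi, rr_min = 0.3, rr_max = 1.2)
  expect_equal(out$mask, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(out$reason[!out$mask], c("range", "range"))
  expect_identical(out$intervals, bi$intervals)  # values untouched
  # boundary values accepted
  expect_true(all(filter_range(build_intervals(c(0, 0.3, 1.5)),
                               rr_min = 0.3, rr_max = 1.2)$mask))
  # all-inside input is identity
  clean <- fixture_rr(100, seed = 1)
  expect_identical(filter_range(clean, rr_min = 0.3, rr_max = 1.2), clean)
})

test_that("moving-average filter rejects a doubled interval, not constants", {
  v <- rep(0.5, 41); v[21] <- 1.0
  bi <- build_intervals(cumsum(c(0, v)))
  out <- filter_moving_average(bi, maf_window = 21L, maf_pct = 0.4)
  # window mean excluding the centre is 0.5; |1.0 - 0.5| > 0.4 * 0.5
  expect_false(out$mask[21])
  expect_true(all(out$mask[-21]))
  const <- build_intervals(cumsum(c(0, rep(0.7, 50))))
  expect_true(all(filter_moving_average(const)$mask))
  # a permissive threshold rejects nothing on mild data
  mild <- fixture_rr(200, seed = 3)
  expect_true(all(filter_moving_average(mild, maf_pct = 0.99)$mask))
})

test_that("quotient filter tests both neighbours at ratio bounds", {
  bi <- build_intervals(cumsum(c(0, 0.5, 1.0, 0.5)))
  out <- filter_quotient(bi, qf_r = 0.8)
  # 1.0/0.5 = 2 > 1/0.8: the centre (and its neighbours, by symmetry of the
  # ratio test) trip the filter
  expect_false(out$mask[2])
  one <- build_intervals(c(0, 0.8))
  expect_true(all(filter_quotient(one)$mask))
  const <- build_intervals(cumsum(c(0, rep(0.6, 20))))
  expect_true(all(filter_quotient(const)$mask))
})

test_that("filter cascade recovers injected ectopics with no false positives", {
  rr <- build_intervals(cumsum(c(0, rep(0.6, 800))))  # clean constant record
  pk <- gen_peak_times(rr, ectopic_rate = 0.04, seed = 21)
  filt <- filter_cascade(build_intervals(pk), filter_config(rr_min = 0.3,
                                                            rr_max = 1.2))
  flagged <- which(!filt$mask)
  truth <- pk$ectopic_intervals
  expect_gte(length(intersect(flagged, truth)) / length(truth), 0.9)
  # no flags outside the contaminated neighbourhood (the quotient filter
  # legitimately tests each boundary interval against a perturbed neighbour)
  neighbourhood <- unique(sort(c(truth - 1L, truth, truth + 1L)))
  expect_length(setdiff(flagged, neighbourhood), 0)
})

test_that("transient removal cuts an initial drift where the oracle says", {
  # 15 s linear drift from 0.9 s down to a steady 0.6 s level
  drift <- seq(0.9, 0.62, length.out = 20)
  v <- c(drift, rep(0.6, 500))
  bi <- build_intervals(cumsum(c(0, v)))
  cfg <- transient_config(lowpass_window = 10, threshold_skip = 30,
                          tolerance = 0.05, target_duration = 300)
  out <- remove_transient(bi, cfg)
  cut_oracle <- naive_transient_cut(bi$times, bi$intervals, 10, 30, 0.05)
  expect_equal(out$times[1L], bi$times[cut_oracle])
  expect_lt(out$times[1L], 20)  # within the first 20 s
  expect_lte(out$times[length(out$times)] - out$times[1L], 300)
  # stationary series: nothing removed beyond the 300 s trim
  stat <- build_intervals(cumsum(c(0, rep(0.6, 600))))
  trimmed <- remove_transient(stat, cfg)
  expect_equal(trimmed$times[1L], 0)
  expect_lte(diff(range(trimmed$times)), 300)
  # a segment too short to define the steady-state level errors
  stub <- build_intervals(cumsum(c(0, rep(0.6, 20))))  # 12 s
  expect_error(remove_transient(stub, cfg), "shorter")
  # coarse alternation whose 10-s sliding means never land near the mean
  runaway <- build_intervals(cumsum(c(0, rep(c(5, 5, 40), 8))))
  expect_error(remove_transient(runaway, cfg), "unusable")
})

test_that("segment_windows drops the trailing partial window", {
  rr25 <- build_intervals(cumsum(c(0, rep(0.5, 3000))))  # 25 min
  expect_length(segment_windows(rr25, 600), 2L)
  short <- build_intervals(cumsum(c(0, rep(0.5, 100))))
  expect_length(segment_windows(short, 600), 0L)
  exact <- build_intervals(cumsum(c(0, rep(0.5, 600))))  # 300 s total
  w <- segment_windows(exact, 300)
  expect_length(w, 1L)
  expect_length(w[[1L]]$intervals, 600L)
})

test_that("segment_windows conserves accepted time up to the partial tail", {
  rr <- fixture_rr(n = 2000, seed = 13)
  w <- segment_windows(rr, 120)
  total <- sum(vapply(w, function(x) sum(accepted(x)), numeric(1)))
  expect_lte(sum(accepted(rr)) - total, 120 + max(rr$intervals))
  expect_gte(total, length(w) * 120 - max(rr$intervals) * length(w))
})

test_that("window QC applies the mu +/- 2 sigma rule", {
  mk <- function(mu, sigma, n = 400) {
    # alternating +/- sigma: sample mean mu, sd ~ sigma
    build_intervals(cumsum(c(0, rep(c(mu - sigma, mu + sigma), n / 2))))
  }
  expect_true(qc_window(mk(0.8, 0.1), rr_min = 0.5, rr_max = 1.2))
  expect_false(qc_window(mk(1.1, 0.1), rr_min = 0.5, rr_max = 1.2))   # high
  expect_false(qc_window(mk(0.65, 0.1), rr_min = 0.5, rr_max = 1.2))  # low
  const <- build_intervals(cumsum(c(0, rep(0.8, 50))))
  expect_true(qc_window(const, rr_min = 0.5, rr_max = 1.2))
})

test_that("interval files round-trip with comments and a rejection log", {
  rr <- filter_range(build_intervals(cumsum(c(1, 0.25, 0.6, 0.62, 1.3))),
                     rr_min = 0.3, rr_max = 1.2)
  f <- tempfile(); g <- tempfile()
  write_intervals(rr, f, log_path = g)
  vals <- read_rr_file(f)
  expect_equal(vals, accepted(rr))
  log <- read.csv(g)
  expect_equal(log$index, which(!rr$mask))
  expect_true(all(log$reason == "range"))
  writeLines(c("# header", "0.5", "", "0.75"), f)
  expect_equal(read_rr_file(f), c(0.5, 0.75))
  writeLines(c("0.5", "oops"), f)
  expect_error(read_rr_file(f), "non-numeric")
})
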