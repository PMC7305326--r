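test_that("gen_noise draws have the requested moments and validate input", {
  for (kind in c("white", "pink", "brownian")) {
    x <- gen_noise(kind, 1024, mean = 0.8, sd = 0.05, seed = 42)
    expect_s3_class(x, "beat_intervals")
    expect_length(x$intervals, 1024)
    expect_true(all(is.finite(x$intervals)))
    expect_equal(mean(x$intervals), 0.8, tolerance = 1e-10)
    expect_equal(sd(x$intervals), 0.05, tolerance = 1e-6)
    # event times are cumulative sums of intervals
    expect_equal(diff(x$times), x$intervals[-1024], tolerance = 0)
  }
  expect_error(gen_noise("white", 1024, sd = 0), "sd")
  expect_error(gen_noise("white", 8), "at least 16")
  # a huge sd relative to the mean must be rejected, not silently clipped
  expect_error(gen_noise("white", 1024, mean = 0.1, sd = 1, seed = 1),
               "non-positive")
})

test_that("gen_noise is bit-reproducible under a fixed seed", {
  a <- gen_noise("pink", 256, seed = 7)
  b <- gen_noise("pink", 256, seed = 7)
  expect_identical(a, b)
  c <- gen_noise("pink", 256, seed = 8)
  expect_false(identical(a$intervals, c$intervals))
})

test_that("white noise is uncorrelated and brownian differences are white", {
  x <- accepted(gen_noise("white", 4096, seed = 11))
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 3 / sqrt(length(x)))
  b <- accepted(gen_noise("brownian", 4096, seed = 11))
  d <- diff(b)
  sp <- welch_psd(d - mean(d), fs = 1)
  expect_lt(abs(beta_slope(sp)), 0.15)
})

test_that("pink noise PSD slope is close to -1 at n = 4096", {
  betas <- vapply(1:5, function(i) {
    x <- accepted(gen_noise("pink", 4096, seed = 100 + i))
    beta_slope(welch_psd(x - mean(x), fs = 1))
  }, numeric(1))
  expect_true(all(betas > -1.3 & betas < -0.7))
})

test_that("basal surrogate degenerates correctly and shows its sine peaks", {
  # no ANS component: pure slow Brownian-like dynamics
  slow <- gen_surrogate_basal(n = 2048, ans_sd = 0, seed = 5)
  a <- dfa_fit(dfa(slow), c(4, 64))
  expect_equal(a, 1.5, tolerance = 0.2)
  # no SAN component, no sines: white-noise statistics (decreasing MSE)
  wn <- gen_surrogate_basal(n = 2048, san_sd = 0, ans_sd = 0.02,
                            sine_amp = 0, seed = 5)
  m <- mse(wn, max_scale = 10)$sampen
  expect_true(all(diff(m) < 0))
  # full spec: periodogram peaks at f1 and f2
  bsl <- gen_surrogate_basal(n = 2048, seed = 6)
  sp <- rr_psd(bsl, method = "welch", fs = 4, nperseg = 1024)
  for (f0 in c(0.15, 0.35)) {
    band <- sp$freq > f0 - 0.05 & sp$freq < f0 + 0.05
    pk <- sp$freq[band][which.max(sp$psd[band])]
    expect_lt(abs(pk - f0), 0.01)
  }
})

test_that("blockade surrogate is low-variance and slow", {
  abk <- gen_surrogate_abk(n = 2048, seed = 3)
  bsl <- gen_surrogate_basal(n = 2048, seed = 3)
  expect_lt(time_domain(abk)$rmssd, time_domain(bsl)$rmssd)
  m <- mse(abk, max_scale = 10)$sampen
  expect_gt(mean(m[8:10]), mean(m[1:3]))  # increasing trend
  # san_sd = 0 gives a constant series
  const <- gen_surrogate_abk(n = 64, san_sd = 0, seed = 1)
  expect_equal(time_domain(const)$sdnn, 0)
})

test_that("ectopic injection flags ground truth and preserves total time", {
  rr <- fixture_rr(n = 1000, seed = 9)
  pk <- gen_peak_times(rr, ectopic_rate = 0.05, seed = 10)
  n_ect <- length(pk$ectopic_beats)
  expect_gt(n_ect, 25)
  expect_lt(n_ect, 75)
  expect_equal(max(pk$times), rr$end_time, tolerance = 1e-12)
  # perturbed peaks create one short and one long interval each
  bi <- build_intervals(pk)
  expect_true(all(abs(bi$intervals[pk$ectopic_intervals] -
                        rr$intervals[pk$ectopic_intervals]) > 0))
  expect_error(gen_peak_times(rr, ectopic_rate = 0.6), "below 0.5")
})

test_that("round trip through peak times is exact at zero ectopic rate", {
  rr <- fixture_rr(n = 257, seed = 2)
  back <- build_intervals(gen_peak_times(rr, ectopic_rate = 0))
  expect_identical(back$intervals, rr$intervals)
  expect_identical(back$times, rr$times)
})
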