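test_that("transfer function matches hand-expanded coefficients and H(0)", {
  p <- clock_params(gamma1 = 2, gamma2 = 3, k1 = 80, k2 = 120, K = 40)
  tf <- transfer_function(p)
  expect_equal(tf$num, 40)
  q1 <- c(1, 2, 120); q2 <- c(1, 3, 160)  # (m s^2 + gamma s + k + K)
  den <- c(1,
           q1[2] + q2[2],
           q1[3] + q2[3] + q1[2] * q2[2],
           q1[2] * q2[3] + q2[2] * q1[3],
           q1[3] * q2[3] - 40^2)
  expect_equal(tf$den, den)
  expect_equal(Mod(clock_frf(p, 0)), p$K / ((p$k1 + p$K) * (p$k2 + p$K) - p$K^2))
  # K = 0 decouples the masses entirely
  p0 <- clock_params(gamma1 = 2, gamma2 = 3, k1 = 80, k2 = 120, K = 0)
  expect_equal(transfer_function(p0)$num, 0)
  expect_equal(Mod(clock_frf(p0, c(0.1, 1))), c(0, 0))
})

test_that("pulse train has the right count, heights and noise moments", {
  tr <- make_pulse_train(freq = 2, fs = 25, duration = 10)
  expect_equal(sum(tr$u > 0), 20)
  expect_true(all(tr$u %in% c(0, 1)))
  expect_length(tr$u, 250)
  # noisy train: pulse-height mean ~ 1, variance ~ mult + add variance
  trn <- make_pulse_train(freq = 2, fs = 25, duration = 5000, noisy = TRUE,
                          seed = 5)
  heights <- trn$u[make_pulse_train(2, 25, 5000)$u == 1]
  expect_equal(mean(heights), 1, tolerance = 0.01)
  expect_lt(abs(var(heights) - (0.04 + 0.0025)), 0.005)
  expect_error(make_pulse_train(freq = 20, fs = 25, duration = 1), "fs")
})

test_that("simulation is linear, null for zero force or zero coupling", {
  p <- clock_params(gamma1 = 2, gamma2 = 3, k1 = 80, k2 = 120, K = 40)
  tr <- make_pulse_train(1.8, 25, 60)
  expect_equal(simulate_clock(p, numeric(500), 25), numeric(500))
  p0 <- clock_params(gamma1 = 2, gamma2 = 3, k1 = 80, k2 = 120, K = 0)
  expect_equal(max(abs(simulate_clock(p0, tr$u, 25))), 0)
  x1 <- simulate_clock(p, tr$u, 25)
  x2 <- simulate_clock(p, 2 * tr$u, 25)
  expect_equal(x2, 2 * x1, tolerance = 1e-12)
})

test_that("steady-state sine gain matches |H(j omega)|", {
  p <- clock_params(gamma1 = 2, gamma2 = 3, k1 = 80, k2 = 120, K = 40)
  fs <- 25
  tt <- seq(0, 200 - 1 / fs, by = 1 / fs)
  for (f0 in c(0.2, 0.8, 1.5)) {
    x2 <- simulate_clock(p, sin(2 * pi * f0 * tt), fs)
    gain <- (max(x2[tt > 100]) - min(x2[tt > 100])) / 2
    expect_equal(gain, Mod(clock_frf(p, f0)), tolerance = 0.02)
  }
})

test_that("impulse response matches the analytic partial-fraction oracle", {
  p <- clock_params(gamma1 = 2, gamma2 = 3, k1 = 80, k2 = 120, K = 40)
  fs <- 50
  n <- 1000
  u <- c(1, numeric(n - 1))
  x2 <- simulate_clock(p, u, fs)
  # oracle: residue expansion of H(s) over its (distinct) poles; the ZOH
  # input is a width-1/fs unit pulse, i.e. the difference of two step
  # responses: y(t) = sum_r res_r/p_r * (exp(p_r t) - exp(p_r (t - dt)))
  tf <- transfer_function(p)
  poles <- polyroot(rev(tf$den))
  res <- vapply(seq_along(poles), function(i) {
    dprime <- sum(vapply(seq_len(4), function(k)
      (5 - k) * tf$den[k] * poles[i]^(4 - k), complex(1)))
    tf$num / dprime
  }, complex(1))
  tt <- (seq_len(n) - 1) / fs
  dt <- 1 / fs
  oracle <- Re(rowSums(vapply(seq_along(poles), function(i) {
    step <- function(t) ifelse(t < 0, 0 + 0i, res[i] / poles[i] *
                                 (exp(poles[i] * t) - 1))
    step(tt) - step(tt - dt)
  }, complex(n))))
  expect_equal(x2, oracle, tolerance = 1e-6 * max(abs(oracle)))
})

test_that("parameters are recovered from simulated records", {
  fs <- 25
  fgrid <- seq(0.01, 0.5, by = 0.01)
  set.seed(101)
  errs <- vapply(1:3, function(i) {
    p <- clock_params(gamma1 = runif(1, 0.5, 2), gamma2 = runif(1, 0.5, 2),
                      k1 = runif(1, 0.05, 0.5), k2 = runif(1, 5, 30),
                      K = runif(1, 2, 10))
    train <- make_pulse_train(1.8, fs, 600, noisy = TRUE, seed = 200 + i)
    y <- simulate_clock(p, train$u, fs)
    fit <- estimate_clock(y, fs = fs, freq = 1.8, seed = 200 + i)
    err <- log(Mod(clock_frf(fit$params, fgrid))) -
      log(Mod(clock_frf(p, fgrid)))
    sqrt(mean(err^2))
  }, numeric(1))
  expect_true(all(errs < 0.05))
})

test_that("estimation rejects zero-transmission records", {
  expect_error(estimate_clock(numeric(25 * 120), fs = 25, freq = 1.8),
               "zero variance|transmission")
  const <- build_intervals(cumsum(c(0, rep(0.5, 400))))
  expect_error(estimate_clock(const), "zero variance|transmission")
})

test_that("fitted model reproduces the direction of the coupling effect", {
  abk <- gen_surrogate_abk(n = 1024, seed = 3)
  fit <- estimate_clock(abk, fs = 25, seed = 2)
  expect_true(all(unlist(fit$params) > 0))
  # all poles strictly in the left half-plane
  tf <- transfer_function(fit$params)
  expect_true(all(Re(polyroot(rev(tf$den))) < 0))
  sc <- k_scan(fit$params, freq = fit$pulse_freq, duration = 600, settle = 60)
  expect_false(is.unsorted(sc$sdnn))
  expect_false(is.unsorted(sc$vlf_norm))
})
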