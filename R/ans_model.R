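#' ANS-contribution model parameters
#'
#' The generative model of the autonomic contribution to beat intervals: two
#' sinusoids at the respiratory- and baroreflex-peak frequencies embedded in
#' Gaussian white noise.  The overall amplitude is tied to the variance of the
#' target interval series through the mix ratio, and the noise floor to the
#' sinusoid power through a signal-to-noise ratio.
#'
#' @param f1,f2 sine frequencies (Hz), `f1 < f2`; defaults 0.15 and 0.35 Hz
#'   (LF and HF peak locations in canine data).
#' @param alpha_m mix ratio > 0: the contribution's sinusoid component is
#'   scaled to standard deviation `alpha_m * sigma_r` (default 0.5).
#' @param snr_n signal-to-noise ratio > 0 between the sinusoid component and
#'   the additive white noise (default 2).
#' @param seed optional RNG seed for the noise draw.
#' @return A list of class `"ans_params"`.
#' @export
ans_params <- function(f1 = 0.15, f2 = 0.35, alpha_m = 0.5, snr_n = 2,
                       seed = NULL) {
  stopifnot(f1 > 0, f2 > f1, alpha_m > 0, snr_n > 0)
  structure(list(f1 = f1, f2 = f2, alpha_m = alpha_m, snr_n = snr_n,
                 seed = seed),
            class = "ans_params")
}

#' Generate the ANS contribution at given evaluation times
#'
#' Constructs \eqn{x(t) = \sin(2\pi f_1 t) + \sin(2\pi f_2 t)} on `[0, T]`,
#' rescales it to standard deviation \eqn{\sigma'_x = \sigma_r \alpha_m}
#' (moments taken over a dense uniform grid, since the signal is defined in
#' continuous time), sets the white-noise level to
#' \eqn{\sigma_n = \sigma'_x / SNR_n}, and returns
#' \eqn{y(t) = x_s(t) + n(t)} evaluated at `eval_times`, with an independent
#' noise draw per evaluation time.  The expected variance of the result is
#' \eqn{\sigma_r^2 \alpha_m^2 (1 + 1/SNR_n^2)}.
#'
#' @param params an [ans_params].
#' @param sigma_r standard deviation of the target RR series (seconds), > 0.
#' @param eval_times times (seconds) at which to evaluate the contribution.
#' @param t_max upper end of the support `[0, T]` (defaults to
#'   `max(eval_times)`).
#' @param dt grid step for the continuous-time moments (default 0.01 s).
#' @return Numeric vector of contribution values at `eval_times` (seconds).
#' @export
generate_ans <- function(params, sigma_r, eval_times,
                         t_max = max(eval_times), dt = 0.01) {
  stopifnot(inherits(params, "ans_params"), sigma_r > 0,
            all(eval_times >= 0), t_max > 0)
  if (t_max * params$f1 < 1)
    stop("degenerate support: [0, T] is shorter than one cycle of f1")
  x_of <- function(t) sin(2 * pi * params$f1 * t) + sin(2 * pi * params$f2 * t)
  grid <- seq(0, t_max, by = dt)
  xg <- x_of(grid)
  mu_x <- mean(xg)
  sd_x <- stats::sd(xg)
  if (!is.finite(sd_x) || sd_x < 1e-8)
    stop("degenerate sinusoid variance over the support")
  sd_target <- sigma_r * params$alpha_m
  sigma_n <- sd_target / params$snr_n
  x_s <- (x_of(eval_times) - mu_x) * sd_target / sd_x
  noise <- with_seed(params$seed,
                     stats::rnorm(length(eval_times), 0, sigma_n))
  x_s + noise
}

#' Mix the ANS contribution into a blockade-state interval series
#'
#' Samples the ANS-contribution process at the beat times of a blockade
#' (ANS-denervated) interval series and adds it to the interval values, using
#' the blockade series' own interval standard deviation as \eqn{\sigma_r}.
#' Beat times are recomputed by cumulative summation of the new intervals.
#' The result emulates restoring the autonomic signature: low-scale
#' multiscale-entropy values rise and DFA slopes move down toward the basal
#' regime.
#'
#' @param abk a [beat_intervals] object (blockade-like series) with >= 2
#'   accepted intervals and non-zero interval variance.
#' @param params an [ans_params].
#' @return A new [beat_intervals] object with the same number of beats.
#' @export
mix_into <- function(abk, params = ans_params()) {
  stopifnot(inherits(abk, "beat_intervals"), inherits(params, "ans_params"))
  if (sum(abk$mask) < 2L) stop("need at least 2 accepted intervals")
  sigma_r <- stats::sd(accepted(abk))
  if (!is.finite(sigma_r) || sigma_r == 0)
    stop("degenerate input: interval variance is zero")
  t0 <- abk$times[1L]
  y <- generate_ans(params, sigma_r, eval_times = abk$times - t0,
                    t_max = abk$end_time - t0)
  new_int <- abk$intervals + y
  if (any(new_int <= 0))
    stop("mixing produced non-positive intervals; use a smaller alpha_m")
  new_times <- t0 + c(0, cumsum(new_int[-length(new_int)]))
  beat_intervals(new_times, new_int, mask = abk$mask, reason = abk$reason,
                 end_time = t0 + sum(new_int))
}
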