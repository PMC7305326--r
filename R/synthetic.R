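#' Generate ideal noise interval series
#'
#' Seeded generators for the three reference noise classes used to calibrate
#' the fractal metrics: white noise (log-log PSD slope \eqn{\beta = 0}, DFA
#' exponent \eqn{\alpha = 0.5}), pink 1/f noise (\eqn{\beta = -1},
#' \eqn{\alpha = 1}) and Brownian noise (\eqn{\beta = -2},
#' \eqn{\alpha = 1.5}).  The samples are interpreted as beat intervals:
#' event times are cumulative sums of the intervals.
#'
#' Pink noise is synthesized in the frequency domain (spectral amplitude
#' proportional to \eqn{f^{-1/2}}, i.e. power proportional to \eqn{1/f}, with
#' uniform random phases) and inverse-transformed; Brownian noise is the
#' cumulative sum of white noise.  Both are re-standardized to the requested
#' mean and standard deviation, which keeps interval positivity controllable.
#'
#' @param kind one of `"white"`, `"pink"`, `"brownian"`.
#' @param n number of intervals (>= 16).
#' @param mean target sample mean (seconds).
#' @param sd target sample standard deviation (seconds), > 0.
#' @param seed optional RNG seed for reproducibility.
#' @return A [beat_intervals] object with `n` intervals.
#' @export
#' @examples
#' x <- gen_noise("white", n = 256, mean = 0.8, sd = 0.05, seed = 1)
#' mean(x$intervals)
gen_noise <- function(kind = c("white", "pink", "brownian"), n,
                      mean = 0.8, sd = 0.05, seed = NULL) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 16L) stop("`n` must be at least 16")
  if (!is.finite(sd) || sd <= 0) stop("`sd` must be positive")
  if (!is.finite(mean) || mean <= 0) stop("`mean` must be positive")
  x <- with_seed(seed, switch(kind,
    white = stats::rnorm(n),
    pink = pink_unit(n),
    brownian = cumsum(stats::rnorm(n))))
  x <- (x - base::mean(x)) / stats::sd(x) * sd + mean
  if (any(x <= 0))
    stop("requested mean/sd produce non-positive intervals; reduce `sd`")
  intervals_to_series(x)
}

# Unit-scale pink noise by spectral synthesis: amplitude ~ f^(-1/2), random
# phases, Hermitian-symmetric spectrum, inverse FFT.
pink_unit <- function(n) {
  nf <- n %/% 2L
  f <- seq_len(nf)
  amp <- f^(-0.5)
  phase <- stats::runif(nf, 0, 2 * pi)
  half <- amp * exp(1i * phase)
  if (n %% 2L == 0L) half[nf] <- Re(half[nf])  # Nyquist bin must be real
  full <- c(0 + 0i, half,
            if (n %% 2L == 0L) Conj(rev(half[-nf])) else Conj(rev(half)))
  Re(stats::fft(full, inverse = TRUE)) / n
}

# Wrap raw interval values into a beat_intervals whose intervals are exactly
# the diffs of its stored event times (exact round trip with gen_peak_times).
intervals_to_series <- function(x, t0 = 0) {
  build_intervals(t0 + c(0, cumsum(x)))
}

#' Generate a basal-like surrogate interval series
#'
#' Emulates the statistical structure of basal (intact autonomic control)
#' beat intervals: a slowly varying Brownian-like component standing in for
#' the sinoatrial node's long-range dynamics, plus the autonomic signature of
#' two sinusoids (respiratory and baroreflex-like peaks at `f1`, `f2`)
#' embedded in broadband white noise:
#' \deqn{RR_i = b + \sigma_{san} B_i + \sigma_{ans}(\sin 2\pi f_1 t_i +
#'   \sin 2\pi f_2 t_i + w_i)}
#' with \eqn{B} unit-variance Brownian noise and \eqn{w} unit white noise,
#' sampled at nominal beat times \eqn{t_i = i b}.
#'
#' @param n number of beats.
#' @param base_interval mean interval (seconds), > 0.
#' @param san_sd amplitude of the slow Brownian component (seconds), >= 0.
#' @param ans_sd amplitude of the periodic-plus-white component (seconds), >= 0.
#' @param f1,f2 frequencies of the periodic components (Hz), `f1 < f2`.
#' @param sine_amp relative amplitude of each sinusoid within the autonomic
#'   component (default 1; 0 leaves pure white noise).
#' @param seed optional RNG seed.
#' @return A [beat_intervals] object.
#' @export
gen_surrogate_basal <- function(n = 2048, base_interval = 0.55,
                                san_sd = 0.03, ans_sd = 0.025,
                                f1 = 0.15, f2 = 0.35, sine_amp = 1,
                                seed = NULL) {
  stopifnot(base_interval > 0, san_sd >= 0, ans_sd >= 0, f1 < f2, n >= 16,
            sine_amp >= 0)
  x <- with_seed(seed, {
    san <- if (san_sd > 0) unit_scale(cumsum(stats::rnorm(n))) else numeric(n)
    w <- stats::rnorm(n)
    tt <- (seq_len(n) - 1) * base_interval
    base_interval + san_sd * san +
      ans_sd * (sine_amp * (sin(2 * pi * f1 * tt) + sin(2 * pi * f2 * tt)) + w)
  })
  if (any(x <= 0))
    stop("surrogate parameters produce non-positive intervals")
  intervals_to_series(x)
}

#' Generate a blockade-like surrogate interval series
#'
#' Emulates beat intervals under double autonomic blockade: a slowly varying
#' Brownian-like series with only very small beat-to-beat variation and no
#' periodic components.  The broadband component amplitude is fixed at
#' `ans_frac * san_sd`.
#'
#' @inheritParams gen_surrogate_basal
#' @param ans_frac residual broadband amplitude as a fraction of `san_sd`.
#' @return A [beat_intervals] object.
#' @export
gen_surrogate_abk <- function(n = 2048, base_interval = 0.5, san_sd = 0.02,
                              ans_frac = 0.05, seed = NULL) {
  stopifnot(base_interval > 0, san_sd >= 0, ans_frac >= 0, n >= 16)
  x <- with_seed(seed, {
    san <- if (san_sd > 0) unit_scale(cumsum(stats::rnorm(n))) else numeric(n)
    base_interval + san_sd * san + ans_frac * san_sd * stats::rnorm(n)
  })
  if (any(x <= 0))
    stop("surrogate parameters produce non-positive intervals")
  intervals_to_series(x)
}

unit_scale <- function(x) (x - mean(x)) / stats::sd(x)

#' Peak-time series with injected ectopic beats
#'
#' Converts a [beat_intervals] series back to R-peak detection times and
#' perturbs a stated fraction of interior beats to emulate ectopy: each
#' selected peak is shifted earlier by `shift_frac` of the preceding interval,
#' shortening one interval and lengthening the next by the same amount
#' (mimicking a premature beat followed by a compensatory pause; total record
#' time is preserved).  Ground-truth indices are returned for filter testing.
#'
#' @param x a [beat_intervals] object.
#' @param ectopic_rate fraction of beats to perturb, in `[0, 0.5)`.
#' @param seed optional RNG seed.
#' @param shift_frac fraction of the preceding interval by which a selected
#'   peak is moved earlier (default 0.45, enough to trip the quotient filter).
#' @return An object of class `"peak_times"`: a list with `times` (peak times,
#'   seconds), `ectopic_beats` (indices of perturbed peaks) and
#'   `ectopic_intervals` (indices of the intervals those perturbations alter).
#' @export
gen_peak_times <- function(x, ectopic_rate = 0, seed = NULL,
                           shift_frac = 0.45) {
  stopifnot(inherits(x, "beat_intervals"),
            ectopic_rate >= 0, shift_frac > 0, shift_frac < 1)
  if (ectopic_rate >= 0.5) stop("`ectopic_rate` must be below 0.5")
  peaks <- c(x$times, x$end_time)
  n_int <- length(x$intervals)
  sel <- integer(0)
  if (ectopic_rate > 0) {
    sel <- with_seed(seed, {
      cand <- which(stats::runif(n_int) < ectopic_rate)
      cand <- cand[cand >= 2L & cand <= n_int - 1L]  # keep both neighbours
      # drop selections adjacent to an earlier one so perturbations don't stack
      keep <- logical(length(cand))
      last <- -2L
      for (k in seq_along(cand)) {
        if (cand[k] - last >= 2L) { keep[k] <- TRUE; last <- cand[k] }
      }
      cand[keep]
    })
    # peak index sel+1 starts interval sel+1; move it earlier into interval sel
    peaks[sel + 1L] <- peaks[sel + 1L] - shift_frac * x$intervals[sel]
  }
  structure(list(times = peaks,
                 ectopic_beats = sel + 1L,
                 ectopic_intervals = sort(unique(c(sel, sel + 1L)))),
            class = "peak_times")
}

#' @export
print.peak_times <- function(x, ...) {
  cat(sprintf("<peak_times> %d peaks, %d ectopic\n",
              length(x$times), length(x$ectopic_beats)))
  invisible(x)
}
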