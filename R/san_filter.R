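#' Exponentially decaying filter specification
#'
#' A one-sided decaying exponential impulse response
#' \eqn{h(t) = u(t) e^{-\alpha t}} with frequency response
#' \eqn{H(f) = 1/(\alpha + j 2\pi f)}: it passes the lowest frequencies and
#' applies a monotonically decaying attenuation to the rest of the spectrum,
#' which attenuates the broadband/periodic autonomic contribution while
#' keeping the slow sinoatrial component.  The decay rate is specified by the
#' value the exponential should reach (`decay_to`) within a time `horizon`.
#'
#' @param decay_to target residual value of the exponential, in (0, 1)
#'   (default 1e-3).
#' @param horizon time (seconds) at which `decay_to` is reached (default 75).
#' @param dc_normalize scale the discrete filter to unit DC gain so the mean
#'   interval is preserved (default `TRUE`).
#' @return A list of class `"exp_filter_spec"`.
#' @export
exp_filter_spec <- function(decay_to = 1e-3, horizon = 75,
                            dc_normalize = TRUE) {
  stopifnot(decay_to > 0, decay_to < 1, horizon > 0)
  structure(list(decay_to = decay_to, horizon = horizon,
                 dc_normalize = isTRUE(dc_normalize)),
            class = "exp_filter_spec")
}

#' Decay-rate constant of the exponential filter
#'
#' Solves \eqn{e^{-\alpha \cdot horizon} = decay\_to} for
#' \eqn{\alpha = \ln(1/decay\_to)/horizon}.
#'
#' @param spec an [exp_filter_spec].
#' @return Decay rate \eqn{\alpha} in 1/s (about 0.0921 for the defaults).
#' @export
solve_alpha <- function(spec = exp_filter_spec()) {
  stopifnot(inherits(spec, "exp_filter_spec"))
  log(1 / spec$decay_to) / spec$horizon
}

#' Apply the exponentially decaying filter to an interval series
#'
#' Resamples the accepted intervals onto a uniform grid at `fs`, applies the
#' sampled exponential kernel as its exact first-order recursive counterpart
#' \eqn{y_k = a y_{k-1} + x_k} with \eqn{a = e^{-\alpha/f_s}} (O(n), no
#' truncation), optionally normalizes to unit DC gain, interpolates the
#' filtered signal back to the original beat times, and recomputes beat times
#' by cumulative summation of the new intervals.  The recursion is initialized
#' at the steady state for the first sample so a constant input passes
#' through unchanged.  The filter has a nonlinear phase; no zero-phase variant
#' is applied.
#'
#' @param x a [beat_intervals] object with >= 4 accepted intervals.
#' @param spec an [exp_filter_spec].
#' @param fs resampling rate (Hz), default 10.
#' @return A new [beat_intervals] object at the accepted beats.
#' @export
apply_exp_filter <- function(x, spec = exp_filter_spec(), fs = 10) {
  stopifnot(inherits(x, "beat_intervals"), inherits(spec, "exp_filter_spec"))
  alpha <- solve_alpha(spec)
  r <- resample_uniform(x, fs, demean = FALSE)
  a <- exp(-alpha / fs)
  # y_k = a y_{k-1} + x_k, started at the constant-input steady state
  y <- stats::filter(r$y, filter = a, method = "recursive",
                     init = r$y[1L] / (1 - a))
  y <- as.numeric(y)
  if (spec$dc_normalize) y <- y * (1 - a)
  tt <- accepted_times(x)
  new_int <- stats::approx(r$t, y, xout = tt, rule = 2)$y
  if (any(new_int <= 0)) stop("filtered intervals became non-positive")
  t0 <- tt[1L]
  new_times <- t0 + c(0, cumsum(new_int[-length(new_int)]))
  beat_intervals(new_times, new_int, end_time = t0 + sum(new_int))
}

#' Frequency response of the discretized exponential filter
#'
#' Magnitude of the first-order recursion used by [apply_exp_filter()] at
#' given frequencies, \eqn{|g / (1 - a e^{-j 2 \pi f / f_s})|} with
#' \eqn{a = e^{-\alpha/f_s}} and gain \eqn{g = 1 - a} under DC normalization
#' (or \eqn{g = 1/f_s} without, matching the continuous kernel's
#' \eqn{1/(\alpha + j 2\pi f)} at low frequency).
#'
#' @param spec an [exp_filter_spec].
#' @param f frequencies (Hz).
#' @param fs sampling rate (Hz).
#' @return Numeric vector of gains.
#' @export
exp_filter_gain <- function(spec, f, fs = 10) {
  alpha <- solve_alpha(spec)
  a <- exp(-alpha / fs)
  g <- if (spec$dc_normalize) 1 - a else 1 / fs
  Mod(g / (1 - a * exp(-2i * pi * f / fs)))
}
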