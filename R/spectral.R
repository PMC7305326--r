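#' Spectral band configuration
#'
#' Frequency bands for RR spectral analysis: the classical VLF/LF/HF triplet
#' plus the two "invariant" bands Ex-A and Ex-B whose normalized power is
#' insensitive to autonomic blockade.
#'
#' @param vlf,lf,hf numeric length-2 `[low, high]` band edges in Hz, ordered
#'   and non-overlapping.
#' @param ex_a,ex_b invariant-band edges in Hz.
#' @return A list of class `"band_config"`.
#' @export
band_config <- function(vlf = c(0.003, 0.04), lf = c(0.04, 0.15),
                        hf = c(0.15, 0.6),
                        ex_a = c(0.045, 0.075), ex_b = c(0.075, 0.105)) {
  chk <- function(b) length(b) == 2L && b[1L] >= 0 && b[1L] < b[2L]
  stopifnot(chk(vlf), chk(lf), chk(hf), chk(ex_a), chk(ex_b),
            vlf[2L] <= lf[1L], lf[2L] <= hf[1L])
  structure(list(vlf = vlf, lf = lf, hf = hf, ex_a = ex_a, ex_b = ex_b),
            class = "band_config")
}

#' Resample an interval series onto a uniform time grid
#'
#' Interpolates accepted interval values against their beat times with a
#' piecewise-cubic spline and evaluates on a uniform grid at `fs`.  Gaps left
#' by rejected intervals are bridged by the interpolant.  This is the standard
#' prerequisite for spectral analysis of the unevenly sampled RR tachogram.
#'
#' @param x a [beat_intervals] object with >= 4 accepted intervals.
#' @param fs target sampling rate (Hz).
#' @param demean subtract the mean after resampling (default `FALSE`).
#' @return List with `t` (grid times, s), `y` (interval values, s), `fs`.
#' @export
resample_uniform <- function(x, fs, demean = FALSE) {
  stopifnot(inherits(x, "beat_intervals"), fs > 0)
  tt <- accepted_times(x)
  v <- accepted(x)
  if (length(v) < 4L) stop("need at least 4 accepted intervals")
  if (diff(range(tt)) < 2 / fs) stop("window too short for rate ", fs, " Hz")
  grid <- seq(tt[1L], tt[length(tt)], by = 1 / fs)
  y <- stats::spline(tt, v, xout = grid, method = "fmm")$y
  if (demean) y <- y - mean(y)
  list(t = grid, y = y, fs = fs)
}

#' Welch power spectral density
#'
#' Segment-averaged, Hann-windowed, one-sided periodogram.  Scaled so that the
#' integral of the PSD over frequency equals the signal variance (Parseval,
#' within windowing tolerance).
#'
#' @param y numeric signal (uniformly sampled).
#' @param fs sampling rate (Hz).
#' @param nperseg segment length (defaults to `length(y)` capped at 1024,
#'   i.e. a plain periodogram for short signals).
#' @param overlap fractional segment overlap (default 0.5).
#' @param demean subtract the overall mean first (default `TRUE`).
#' @return A `"spectral_estimate"`: list with `freq` (Hz), `psd` (power per
#'   Hz in the squared units of `y`), `method`, `fs`.
#' @export
welch_psd <- function(y, fs = 1, nperseg = NULL, overlap = 0.5,
                      demean = TRUE) {
  n <- length(y)
  if (demean) y <- y - mean(y)
  nperseg <- min(as.integer(nperseg %||% min(n, 1024L)), n)
  stopifnot(nperseg >= 8L, overlap >= 0, overlap < 1)
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))  # Hann
  u <- sum(w^2)
  nf <- nperseg %/% 2L
  acc <- numeric(nf + 1L)
  for (s in starts) {
    seg <- y[s:(s + nperseg - 1L)] * w
    p <- Mod(stats::fft(seg))^2 / (fs * u)
    acc <- acc + p[seq_len(nf + 1L)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  dbl <- rep(2, nf + 1L); dbl[1L] <- 1
  if (nperseg %% 2L == 0L) dbl[nf + 1L] <- 1
  psd <- psd * dbl
  structure(list(freq = (0:nf) * fs / nperseg, psd = psd,
                 method = "welch", fs = fs, nperseg = nperseg),
            class = "spectral_estimate")
}

#' Autoregressive (Burg) power spectral density
#'
#' Fits an AR model by Burg's method ([stats::ar.burg()]) and evaluates the
#' one-sided model spectrum on a uniform frequency grid.
#'
#' @inheritParams welch_psd
#' @param order AR model order.
#' @param nfreq number of frequency points on `[0, fs/2]`.
#' @return A `"spectral_estimate"` (see [welch_psd()]) with `ar_order` set.
#' @export
burg_psd <- function(y, fs = 1, order = 16, nfreq = 512, demean = TRUE) {
  n <- length(y)
  if (order >= n) stop("AR order must be below the sample count")
  if (demean) y <- y - mean(y)
  fit <- stats::ar.burg(y, aic = FALSE, order.max = order, demean = FALSE)
  a <- fit$ar
  freq <- seq(0, fs / 2, length.out = nfreq)
  ew <- exp(-2i * pi * outer(freq / fs, seq_along(a)))
  denom <- Mod(1 - as.vector(ew %*% a))^2
  psd <- 2 * fit$var.pred / fs / denom  # one-sided
  psd[1L] <- psd[1L] / 2
  structure(list(freq = freq, psd = psd, method = "ar", fs = fs,
                 ar_order = order),
            class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> %s, %d bins, 0-%.3g Hz\n",
              x$method, length(x$freq), max(x$freq)))
  invisible(x)
}

#' @export
plot.spectral_estimate <- function(x, log = "xy", ...) {
  keep <- x$freq > 0 & x$psd > 0
  graphics::plot(x$freq[keep], x$psd[keep], type = "l", log = log,
                 xlab = "frequency (Hz)", ylab = "PSD", ...)
  invisible(x)
}

#' Power spectral density of a beat-interval window
#'
#' Resamples the accepted intervals onto a uniform grid (see
#' [resample_uniform()]) and estimates the PSD of the mean-removed tachogram,
#' by default with an autoregressive (Burg) model as is conventional for
#' short HRV windows.
#'
#' @param x a [beat_intervals] object.
#' @param method `"ar"` (Burg, default) or `"welch"`.
#' @param fs resampling rate (Hz); 10 Hz suits canine HF bands, 4 Hz human.
#' @param ar_order AR model order (method `"ar"`).
#' @param nperseg Welch segment length (method `"welch"`).
#' @return A `"spectral_estimate"` with PSD in s^2/Hz.
#' @export
rr_psd <- function(x, method = c("ar", "welch"), fs = 10, ar_order = 16,
                   nperseg = NULL) {
  method <- match.arg(method)
  r <- resample_uniform(x, fs, demean = TRUE)
  switch(method,
         ar = burg_psd(r$y, fs = fs, order = ar_order, demean = FALSE),
         welch = welch_psd(r$y, fs = fs, nperseg = nperseg, demean = FALSE))
}

# Integrate a PSD over [lo, hi] by trapezoid rule, interpolating the exact
# band edges so adjacent bands partition their union exactly.
band_integral <- function(spec, lo, hi) {
  f <- spec$freq; p <- spec$psd
  if (hi <= f[1L] || lo >= f[length(f)])
    stop(sprintf("band [%g, %g] lies outside the frequency range", lo, hi))
  lo <- max(lo, f[1L]); hi <- min(hi, f[length(f)])
  inside <- f > lo & f < hi
  fb <- c(lo, f[inside], hi)
  pb <- c(stats::approx(f, p, lo)$y, p[inside], stats::approx(f, p, hi)$y)
  sum(diff(fb) * (utils::head(pb, -1) + utils::tail(pb, -1)) / 2)
}

#' Band power decomposition of an RR spectrum
#'
#' Absolute power (ms^2) per band by trapezoid integration of the PSD,
#' normalized power (fraction of VLF+LF+HF), per-band peak frequency, the
#' LF/HF ratio, total power over `[vlf_low, hf_high]`, and the normalized
#' power of the invariant bands Ex-A and Ex-B.
#'
#' @param spec a `"spectral_estimate"` with PSD in s^2/Hz.
#' @param bands a [band_config].
#' @return Named list: `vlf_power`, `lf_power`, `hf_power` (ms^2), `vlf_norm`,
#'   `lf_norm`, `hf_norm`, `vlf_peak`, `lf_peak`, `hf_peak` (Hz), `lf_hf`,
#'   `total_power` (ms^2), `ex_a_norm`, `ex_b_norm`.
#' @export
band_powers <- function(spec, bands = band_config()) {
  stopifnot(inherits(spec, "spectral_estimate"), inherits(bands, "band_config"))
  to_ms2 <- 1e6
  pow <- function(b) band_integral(spec, b[1L], b[2L]) * to_ms2
  peak <- function(b) {
    idx <- which(spec$freq >= b[1L] & spec$freq <= b[2L])
    if (!length(idx)) return(NA_real_)
    spec$freq[idx[which.max(spec$psd[idx])]]
  }
  vlf <- pow(bands$vlf); lf <- pow(bands$lf); hf <- pow(bands$hf)
  denom <- vlf + lf + hf
  list(vlf_power = vlf, lf_power = lf, hf_power = hf,
       vlf_norm = vlf / denom, lf_norm = lf / denom, hf_norm = hf / denom,
       vlf_peak = peak(bands$vlf), lf_peak = peak(bands$lf),
       hf_peak = peak(bands$hf),
       lf_hf = lf / hf,
       total_power = band_integral(spec, bands$vlf[1L], bands$hf[2L]) * to_ms2,
       ex_a_norm = pow(bands$ex_a) / denom,
       ex_b_norm = pow(bands$ex_b) / denom)
}

#' Spectral fractal exponent (log-log PSD slope)
#'
#' Least-squares slope of `log10(PSD)` against `log10(f)`, the fractal
#' exponent \eqn{\beta} (0 for white noise, -1 for pink, -2 for Brownian).
#' By default the fit uses log-uniform frequency binning (points averaged
#' within equal bins of `log10 f`) so every octave contributes equally, the
#' standard practice when estimating power-law exponents from spectra whose
#' linear grid crowds the high-frequency end.
#'
#' @param spec a `"spectral_estimate"`.
#' @param band optional `[low, high]` Hz restriction; default is the full
#'   resolvable band (all positive-frequency bins).
#' @param logbin average bins log-uniformly before fitting (default `TRUE`).
#' @param bins_per_decade number of log bins per frequency decade.
#' @return The fitted slope (dimensionless); `NA` if fewer than 5 usable bins.
#' @export
beta_slope <- function(spec, band = NULL, logbin = TRUE,
                       bins_per_decade = 10) {
  stopifnot(inherits(spec, "spectral_estimate"))
  keep <- spec$freq > 0 & spec$psd > 0
  if (!is.null(band)) keep <- keep & spec$freq >= band[1L] & spec$freq <= band[2L]
  f <- log10(spec$freq[keep]); p <- log10(spec$psd[keep])
  if (length(f) < 5L) return(NA_real_)
  if (logbin) {
    br <- seq(min(f), max(f), length.out = max(
      3L, ceiling((max(f) - min(f)) * bins_per_decade)))
    g <- cut(f, breaks = br, include.lowest = TRUE)
    f <- tapply(f, g, mean); p <- tapply(p, g, mean)
    ok <- !is.na(f); f <- f[ok]; p <- p[ok]
    if (length(f) < 3L) return(NA_real_)
  }
  unname(stats::coef(stats::lm(p ~ f))[2L])
}
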