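#' Full HRV metric report for one analysis window
#'
#' Computes the complete metric battery on the accepted intervals of a
#' window: time-domain metrics, autoregressive band powers, the spectral
#' fractal exponent beta (fitted on the Welch periodogram of the resampled
#' tachogram over the VLF band by default), sample entropy, the multiscale
#' entropy curve and the DFA curve with its two slopes and base level.
#'
#' @param x a [beat_intervals] window.
#' @param preset a [species_preset()] list supplying filter bands, pNN
#'   threshold and resampling rate; individual pieces can be overridden.
#' @param bands a [band_config] (default from `preset`).
#' @param pnn_ms pNN threshold in ms (default from `preset`).
#' @param fs resampling rate in Hz (default from `preset`).
#' @param ar_order AR model order for the band-power spectrum.
#' @param max_scale largest MSE scale.
#' @param m,r sample-entropy template length and tolerance fraction.
#' @param beta_band `[low, high]` Hz band for the beta fit; default the VLF
#'   band.
#' @return An object of class `"hrv_report"`: list with `metrics` (named
#'   numeric vector using the conventional metric names), `mse`
#'   (an `"mse_curve"`), `dfa` (a `"dfa_curve"`), and `spectrum`.
#' @export
hrv_report <- function(x, preset = species_preset("canine"),
                       bands = preset$bands, pnn_ms = preset$pnn_ms,
                       fs = preset$resample_fs, ar_order = 16,
                       max_scale = 20L, m = 2L, r = 0.2,
                       beta_band = bands$vlf) {
  stopifnot(inherits(x, "beat_intervals"))
  td <- time_domain(x, pnn_ms = pnn_ms)
  spec <- rr_psd(x, method = "ar", fs = fs, ar_order = ar_order)
  bp <- band_powers(spec, bands)
  # long Welch segments so the VLF band holds enough bins for the beta fit
  wspec <- rr_psd(x, method = "welch", fs = fs, nperseg = 4096L)
  beta <- beta_slope(wspec, band = beta_band)
  se <- as.numeric(sample_entropy(x, m = m, r = r))
  msec <- mse(x, max_scale = max_scale, m = m, r = r)
  dfac <- dfa(x)
  mse_at <- function(s) if (s <= max_scale) msec$sampen[s] else NA_real_
  metrics <- c(
    AVNN = td$avnn, SDNN = td$sdnn, RMSSD = td$rmssd,
    pNN = td$pnn, SD1 = td$sd1, SD2 = td$sd2,
    `VLF Power` = bp$vlf_power, `LF Power` = bp$lf_power,
    `HF Power` = bp$hf_power,
    `VLF Norm` = bp$vlf_norm, `LF Norm` = bp$lf_norm, `HF Norm` = bp$hf_norm,
    `VLF Peak` = bp$vlf_peak, `LF Peak` = bp$lf_peak, `HF Peak` = bp$hf_peak,
    `LF/HF` = bp$lf_hf, `Tot. Power` = bp$total_power,
    `Ex-A Norm` = bp$ex_a_norm, `Ex-B Norm` = bp$ex_b_norm,
    beta = beta,
    alpha1 = attr(dfac, "alpha1"), alpha2 = attr(dfac, "alpha2"),
    `DFA base` = attr(dfac, "base_level"),
    SampEn = se,
    MSE5 = mse_at(5L), MSE10 = mse_at(10L), MSE15 = mse_at(15L),
    MSE20 = mse_at(20L))
  names(metrics)[4L] <- sprintf("pNN%g", pnn_ms)
  structure(list(metrics = metrics, mse = msec, dfa = dfac, spectrum = spec),
            class = "hrv_report")
}

#' @export
print.hrv_report <- function(x, digits = 4, ...) {
  cat("HRV report\n")
  print(round(x$metrics, digits))
  invisible(x)
}

#' @export
as.data.frame.hrv_report <- function(x, ...) {
  as.data.frame(as.list(x$metrics), check.names = FALSE)
}
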