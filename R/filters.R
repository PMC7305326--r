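#' Interval-filter configuration
#'
#' Bundles the thresholds of the three ectopic-beat filters: range-based
#' filtering (RBF), moving-average filtering (MAF) and quotient filtering (QF).
#'
#' @param rr_min,rr_max RBF acceptance range (seconds); boundaries inclusive.
#' @param maf_window MAF window size in samples (odd, >= 3); the tested sample
#'   is excluded from the window mean.
#' @param maf_pct MAF rejection threshold as a fraction of the window mean.
#' @param qf_r QF tolerance ratio in (0, 1); an interval is rejected when the
#'   ratio to its predecessor or successor falls outside `[qf_r, 1/qf_r]`.
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(rr_min = 0.3, rr_max = 1.2, maf_window = 21L,
                          maf_pct = 0.4, qf_r = 0.8) {
  stopifnot(rr_min < rr_max, rr_min > 0,
            maf_window >= 3L, maf_window %% 2L == 1L,
            maf_pct > 0, maf_pct < 1, qf_r > 0, qf_r < 1)
  structure(list(rr_min = rr_min, rr_max = rr_max,
                 maf_window = as.integer(maf_window),
                 maf_pct = maf_pct, qf_r = qf_r),
            class = "filter_config")
}

#' Species / study presets
#'
#' Bundled analysis presets: RR range filters, spectral bands, pNN threshold
#' and resampling rate appropriate for canine data, long-term human ambulatory
#' (Holter) data, and short human pharmacological-blockade recordings.
#'
#' @param species one of `"canine"`, `"human"`, `"human_blockade"`.
#' @return A list with elements `filter` ([filter_config]), `bands`
#'   ([band_config]), `pnn_ms` (pNN threshold, ms), `resample_fs` (Hz) and
#'   `window_sec` (analysis window length, seconds).
#' @export
species_preset <- function(species = c("canine", "human", "human_blockade")) {
  species <- match.arg(species)
  switch(species,
    canine = list(
      filter = filter_config(rr_min = 0.3, rr_max = 1.2),
      bands = band_config(vlf = c(0.003, 0.04), lf = c(0.04, 0.15),
                          hf = c(0.15, 0.6)),
      pnn_ms = 32, resample_fs = 10, window_sec = 300),
    human = list(
      filter = filter_config(rr_min = 0.5, rr_max = 1.2),
      bands = band_config(vlf = c(0.0033, 0.04), lf = c(0.04, 0.15),
                          hf = c(0.15, 0.4)),
      pnn_ms = 50, resample_fs = 4, window_sec = 600),
    human_blockade = list(
      filter = filter_config(rr_min = 0.5, rr_max = 1.5),
      bands = band_config(vlf = c(0.0033, 0.04), lf = c(0.04, 0.15),
                          hf = c(0.15, 0.4)),
      pnn_ms = 50, resample_fs = 4, window_sec = 300))
}

#' Range-based filtering (RBF)
#'
#' Rejects intervals whose duration lies outside `[rr_min, rr_max]`
#' (boundaries accepted).
#'
#' @param x a [beat_intervals] object.
#' @param cfg a [filter_config], or `NULL` to use `rr_min`/`rr_max` directly.
#' @param rr_min,rr_max acceptance range (seconds), used when `cfg` is `NULL`.
#' @return The input with out-of-range intervals masked (reason `"range"`).
#' @export
filter_range <- function(x, cfg = NULL, rr_min = 0.3, rr_max = 1.2) {
  stopifnot(inherits(x, "beat_intervals"))
  if (!is.null(cfg)) { rr_min <- cfg$rr_min; rr_max <- cfg$rr_max }
  bad <- which(x$intervals < rr_min | x$intervals > rr_max)
  reject_intervals(x, bad, "range")
}

#' Moving-average filtering (MAF)
#'
#' Rejects interval i when its deviation from the local window mean exceeds
#' `maf_pct` of that mean.  The window covers `(maf_window - 1)/2` samples on
#' each side; the tested sample itself is excluded from the mean so that an
#' outlier cannot shield itself.  Edge windows are truncated.
#'
#' @inheritParams filter_range
#' @param maf_window,maf_pct see [filter_config()].
#' @return The input with offending intervals masked (reason `"moving_average"`).
#' @export
filter_moving_average <- function(x, cfg = NULL, maf_window = 21L,
                                  maf_pct = 0.4) {
  stopifnot(inherits(x, "beat_intervals"))
  if (!is.null(cfg)) { maf_window <- cfg$maf_window; maf_pct <- cfg$maf_pct }
  stopifnot(maf_window %% 2L == 1L, maf_window >= 3L)
  v <- x$intervals
  n <- length(v)
  h <- (maf_window - 1L) %/% 2L
  cs <- c(0, cumsum(v))
  lo <- pmax(1L, seq_len(n) - h)
  hi <- pmin(n, seq_len(n) + h)
  wmean <- (cs[hi + 1L] - cs[lo] - v) / (hi - lo)  # excludes the centre sample
  bad <- which(abs(v - wmean) > maf_pct * wmean)
  reject_intervals(x, bad, "moving_average")
}

#' Quotient filtering (QF)
#'
#' Rejects interval i when the ratio to its predecessor or its successor lies
#' outside `[r, 1/r]`.  An interval adjacent to a rejected one is still tested
#' against the neighbour's raw value.
#'
#' @inheritParams filter_range
#' @param qf_r tolerance ratio in (0, 1).
#' @return The input with offending intervals masked (reason `"quotient"`).
#' @export
filter_quotient <- function(x, cfg = NULL, qf_r = 0.8) {
  stopifnot(inherits(x, "beat_intervals"))
  if (!is.null(cfg)) qf_r <- cfg$qf_r
  stopifnot(qf_r > 0, qf_r < 1)
  v <- x$intervals
  n <- length(v)
  if (n < 2L) return(x)
  ratio_prev <- c(NA, v[-1L] / v[-n])
  ratio_next <- c(v[-n] / v[-1L], NA)
  out <- function(r) !is.na(r) & (r < qf_r | r > 1 / qf_r)
  bad <- which(out(ratio_prev) | out(ratio_next))
  reject_intervals(x, bad, "quotient")
}

#' Apply the full RBF + MAF + QF cascade
#'
#' @inheritParams filter_range
#' @param cfg a [filter_config].
#' @return The input with all three filters' rejections applied.
#' @export
filter_cascade <- function(x, cfg = filter_config()) {
  x <- filter_range(x, cfg)
  x <- filter_moving_average(x, cfg)
  filter_quotient(x, cfg)
}

#' Transient-removal configuration
#'
#' @param lowpass_window sliding-mean window length (seconds).
#' @param threshold_skip time (seconds) after which the segment is assumed
#'   transient-free; the steady-state threshold is the mean interval from this
#'   point onward.
#' @param tolerance relative tolerance: the transient ends at the first
#'   position where the sliding mean is within `tolerance * threshold`.
#' @param target_duration duration (seconds) to which the remaining segment is
#'   trimmed.
#' @return A list of class `"transient_config"`.
#' @export
transient_config <- function(lowpass_window = 10, threshold_skip = 30,
                             tolerance = 0.05, target_duration = 300) {
  stopifnot(lowpass_window > 0, threshold_skip > 0, tolerance > 0,
            target_duration > 0)
  structure(list(lowpass_window = lowpass_window,
                 threshold_skip = threshold_skip,
                 tolerance = tolerance, target_duration = target_duration),
            class = "transient_config")
}

#' Remove the post-intervention rate transient from a segment
#'
#' A heart-rate transient follows pharmacological intervention.  The
#' steady-state level is estimated as the mean interval from `threshold_skip`
#' seconds onward; a sliding mean over `lowpass_window` seconds is scanned from
#' the segment start, and the series is cut at the first beat whose sliding
#' mean is within `tolerance` (relative) of the steady-state level.  The
#' remainder is trimmed to `target_duration` seconds.
#'
#' @param x a [beat_intervals] object spanning more than
#'   `cfg$threshold_skip` seconds.
#' @param cfg a [transient_config].
#' @return A new, shorter [beat_intervals] object.
#' @export
remove_transient <- function(x, cfg = transient_config()) {
  stopifnot(inherits(x, "beat_intervals"), inherits(cfg, "transient_config"))
  t0 <- x$times[1L]
  elapsed <- x$end_time - t0
  if (elapsed <= cfg$threshold_skip)
    stop("segment shorter than `threshold_skip`; cannot estimate steady state")
  steady <- x$intervals[x$times - t0 >= cfg$threshold_skip]
  if (!length(steady)) stop("no intervals after `threshold_skip`")
  thr <- mean(steady)
  n <- length(x$intervals)
  cut <- NA_integer_
  for (i in seq_len(n)) {
    in_win <- x$times >= x$times[i] & x$times < x$times[i] + cfg$lowpass_window
    m <- mean(x$intervals[in_win])
    if (abs(m - thr) <= cfg$tolerance * thr) { cut <- i; break }
  }
  if (is.na(cut))
    stop("unusable segment: sliding mean never reaches the steady-state level")
  keep <- seq.int(cut, n)
  y <- beat_intervals(x$times[keep], x$intervals[keep],
                      mask = x$mask[keep], reason = x$reason[keep],
                      end_time = x$end_time)
  trim <- y$times - y$times[1L] < cfg$target_duration
  if (!all(trim)) {
    keep2 <- which(trim)
    y <- beat_intervals(y$times[keep2], y$intervals[keep2],
                        mask = y$mask[keep2], reason = y$reason[keep2])
  }
  y
}

#' Split a record into consecutive analysis windows
#'
#' Windows are non-overlapping and defined by elapsed time from the first
#' beat; a trailing window not fully covered by the record is dropped.
#'
#' @param x a [beat_intervals] object.
#' @param duration window length (seconds), positive.
#' @return A list of [beat_intervals] objects (possibly empty).
#' @export
segment_windows <- function(x, duration) {
  stopifnot(inherits(x, "beat_intervals"), duration > 0)
  t0 <- x$times[1L]
  total <- x$end_time - t0
  n_win <- floor(total / duration)
  if (n_win < 1L) return(list())
  lapply(seq_len(n_win), function(w) {
    lo <- t0 + (w - 1L) * duration
    hi <- lo + duration
    idx <- which(x$times >= lo & x$times < hi)
    beat_intervals(x$times[idx], x$intervals[idx],
                   mask = x$mask[idx], reason = x$reason[idx])
  })
}

#' Window quality control
#'
#' Discards an analysis window when, under a normal approximation, roughly
#' more than 5% of its intervals would fall above `rr_max` or below `rr_min`:
#' the window is kept iff \eqn{\mu + 2\sigma \le RR_{max}} and
#' \eqn{\mu - 2\sigma \ge RR_{min}} over its accepted intervals.
#'
#' @param w a [beat_intervals] window with at least one accepted interval.
#' @param rr_min,rr_max thresholds (seconds).
#' @return `TRUE` to keep the window, `FALSE` to discard it.
#' @export
qc_window <- function(w, rr_min = 0.5, rr_max = 1.2) {
  v <- accepted(w)
  if (!length(v)) stop("window has no accepted intervals")
  mu <- mean(v)
  sdev <- if (length(v) > 1L) stats::sd(v) else 0
  !(mu + 2 * sdev > rr_max || mu - 2 * sdev < rr_min)
}
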