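#' Beat-interval series
#'
#' The central data structure of the package: a series of beat (RR) intervals
#' together with the event time at which each interval starts, a per-interval
#' acceptance mask, and the rejection reason for masked intervals.  Filtering
#' operations never alter interval values; they only flip mask entries.
#'
#' @param times numeric vector of interval start times (seconds), strictly
#'   increasing.
#' @param intervals numeric vector of interval durations (seconds), same
#'   length as `times`.
#' @param mask logical acceptance flags (default all `TRUE`).
#' @param reason character rejection reasons (`NA` for accepted intervals).
#' @param end_time time of the final beat (seconds); defaults to
#'   `times[n] + intervals[n]`.
#'
#' @return An object of class `"beat_intervals"`: a list with elements
#'   `times`, `intervals`, `mask`, `reason`, `end_time`.
#' @seealso [build_intervals()] to construct one from R-peak times.
#' @export
beat_intervals <- function(times, intervals, mask = NULL, reason = NULL,
                           end_time = NULL) {
  times <- as.numeric(times)
  intervals <- as.numeric(intervals)
  n <- length(intervals)
  if (length(times) != n) stop("`times` and `intervals` must have equal length")
  if (n < 1L) stop("need at least one interval")
  if (any(!is.finite(times)) || any(!is.finite(intervals)))
    stop("non-finite times or intervals")
  mask <- mask %||% rep(TRUE, n)
  reason <- reason %||% rep(NA_character_, n)
  structure(
    list(times = times, intervals = intervals,
         mask = as.logical(mask), reason = as.character(reason),
         end_time = end_time %||% (times[n] + intervals[n])),
    class = "beat_intervals"
  )
}

#' Build an RR interval series from R-peak detection times
#'
#' Given R-peak times \eqn{t_0, \dots, t_{N-1}}, the interval series is
#' \eqn{RR(t_i) = t_{i+1} - t_i}, \eqn{i = 0, \dots, N-2}.  All intervals are
#' initially accepted.
#'
#' @param peaks numeric vector of R-peak detection times (seconds), strictly
#'   increasing, length at least 2.  May also be a `"peak_times"` object from
#'   [gen_peak_times()].
#' @return A [beat_intervals] object with `length(peaks) - 1` intervals.
#' @export
#' @examples
#' build_intervals(c(0, 0.5, 1.1))$intervals  # 0.5 0.6
build_intervals <- function(peaks) {
  if (inherits(peaks, "peak_times")) peaks <- peaks$times
  peaks <- as.numeric(peaks)
  if (length(peaks) < 2L) stop("need at least 2 peak times")
  d <- diff(peaks)
  bad <- which(d <= 0)
  if (length(bad)) {
    stop(sprintf("peak times not strictly increasing at index %d", bad[1L] + 1L))
  }
  beat_intervals(times = peaks[-length(peaks)], intervals = d,
                 end_time = peaks[length(peaks)])
}

#' @export
print.beat_intervals <- function(x, ...) {
  n <- length(x$intervals)
  acc <- sum(x$mask)
  cat(sprintf("<beat_intervals> %d intervals (%d accepted), %.1f s elapsed\n",
              n, acc, x$end_time - x$times[1L]))
  cat(sprintf("  mean RR %.3f s, sd %.4f s (accepted)\n",
              mean(x$intervals[x$mask]), stats::sd(x$intervals[x$mask])))
  invisible(x)
}

#' @export
as.data.frame.beat_intervals <- function(x, ...) {
  data.frame(time = x$times, interval = x$intervals,
             accepted = x$mask, reason = x$reason)
}

#' @export
length.beat_intervals <- function(x) length(x$intervals)

#' Accepted interval values
#'
#' @param x a [beat_intervals] object.
#' @return Numeric vector of accepted interval durations (seconds).
#' @export
accepted <- function(x) {
  stopifnot(inherits(x, "beat_intervals"))
  x$intervals[x$mask]
}

#' Accepted interval start times
#' @param x a [beat_intervals] object.
#' @return Numeric vector of start times (seconds) of accepted intervals.
#' @export
accepted_times <- function(x) {
  stopifnot(inherits(x, "beat_intervals"))
  x$times[x$mask]
}

# Mark intervals rejected, keeping any earlier rejection and its reason.
reject_intervals <- function(x, idx, reason) {
  idx <- idx[x$mask[idx]]
  x$mask[idx] <- FALSE
  x$reason[idx] <- reason
  x
}

#' Read beat event times or intervals from a plain-text file
#'
#' One floating-point value per line, in seconds; lines starting with `#` are
#' ignored.
#'
#' @param path file path.
#' @return Numeric vector.
#' @export
read_rr_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) stop("non-numeric line in ", path)
  vals
}

#' Write accepted intervals to a plain-text file
#'
#' Writes one interval per line (seconds).  Optionally also writes a
#' rejection-log CSV with columns `index`, `value`, `reason`.
#'
#' @param x a [beat_intervals] object.
#' @param path output file for accepted interval values.
#' @param log_path optional path for the rejection-log CSV.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, log_path = NULL) {
  stopifnot(inherits(x, "beat_intervals"))
  writeLines(format(x$intervals[x$mask], digits = 15, trim = TRUE,
                    scientific = FALSE), path)
  if (!is.null(log_path)) {
    rej <- which(!x$mask)
    utils::write.csv(
      data.frame(index = rej, value = x$intervals[rej], reason = x$reason[rej]),
      log_path, row.names = FALSE)
  }
  invisible(path)
}
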