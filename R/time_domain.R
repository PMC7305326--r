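#' Time-domain HRV metrics
#'
#' Computes the classical time-domain metric set on the accepted intervals of
#' a window: AVNN (mean NN interval), SDNN (standard deviation), RMSSD
#' (root-mean-square of successive differences), pNNx (% of successive
#' differences exceeding `pnn_ms`), and the Poincare-plot axes
#' \eqn{SD1 = sd(\Delta RR)/\sqrt 2} and \eqn{SD2 = \sqrt{2 SDNN^2 - SD1^2}}.
#' All outputs are in milliseconds except pNN (percent).
#'
#' @param x a [beat_intervals] object with at least 2 accepted intervals (a
#'   single interval yields `AVNN` with the remaining metrics `NA`).
#' @param pnn_ms pNN threshold in milliseconds (32 for canine presets, 50 for
#'   human).
#' @return Named list: `avnn`, `sdnn`, `rmssd`, `pnn`, `sd1`, `sd2`.
#' @export
#' @examples
#' x <- gen_noise("white", 512, seed = 1)
#' time_domain(x)$sdnn
time_domain <- function(x, pnn_ms = 32) {
  stopifnot(inherits(x, "beat_intervals"), pnn_ms > 0)
  v <- accepted(x) * 1000  # ms
  if (length(v) < 2L) {
    return(list(avnn = if (length(v)) mean(v) else NA_real_,
                sdnn = NA_real_, rmssd = NA_real_, pnn = NA_real_,
                sd1 = NA_real_, sd2 = NA_real_))
  }
  d <- diff(v)
  sdnn <- stats::sd(v)
  sd1 <- stats::sd(d) / sqrt(2)
  list(avnn = mean(v),
       sdnn = sdnn,
       rmssd = sqrt(mean(d^2)),
       pnn = 100 * mean(abs(d) > pnn_ms),
       sd1 = sd1,
       sd2 = sqrt(max(0, 2 * sdnn^2 - sd1^2)))
}
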