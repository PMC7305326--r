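#' Sample entropy
#'
#' SampEn(m, r): the negative logarithm of the conditional probability that
#' two sequences similar for `m` points (Chebyshev distance within the
#' tolerance) remain similar at the (m+1)-th point, self-matches excluded.
#' Template pairs are counted over the first `n - m` start positions so every
#' m-template has an (m+1)-sample extension.
#'
#' @param x numeric series (or a [beat_intervals], whose accepted intervals
#'   are used).
#' @param m template length (default 2).
#' @param r tolerance as a fraction of `sd(x)` (default 0.2); ignored when
#'   `tol` is given.
#' @param tol absolute tolerance; overrides `r` when non-`NULL` (used by
#'   [mse()] to hold the tolerance fixed across scales).
#' @return SampEn value (>= 0); `NaN` with attribute `undefined = TRUE` when
#'   no template matches exist at either length.
#' @export
#' @examples
#' sample_entropy(rep(1, 100))             # 0: everything matches
#' sample_entropy(gen_noise("white", 512, seed = 1))
sample_entropy <- function(x, m = 2L, r = 0.2, tol = NULL) {
  if (inherits(x, "beat_intervals")) x <- accepted(x)
  x <- as.numeric(x)
  n <- length(x)
  if (n <= m + 1L) stop("series too short for template length m")
  if (is.null(tol)) {
    if (r <= 0) stop("`r` must be positive")
    tol <- r * stats::sd(x)
  }
  cnt <- .sampen_counts(x, as.integer(m), as.double(tol))
  b <- cnt[1L]; a <- cnt[2L]
  if (a == 0 || b == 0) {
    return(structure(NaN, undefined = TRUE))
  }
  -log(a / b)
}

#' Multiscale entropy (MSE)
#'
#' Computes SampEn on coarse-grained versions of the series: at scale
#' \eqn{\tau} the series is replaced by the means of consecutive
#' non-overlapping blocks of \eqn{\tau} samples.  The matching tolerance is
#' fixed from the scale-1 series (`r * sd(x)`) and held constant across
#' scales, the convention of the MSE literature.  White noise yields a
#' monotonically decreasing curve, Brownian noise a monotonically increasing
#' one, and pink (1/f) noise stays approximately flat at a high level.
#'
#' @inheritParams sample_entropy
#' @param max_scale largest coarse-graining scale (default 20).
#' @return A data frame of class `"mse_curve"` with columns `scale`,
#'   `sampen` (NaN where undefined); attributes `m`, `r`, `tol`.
#' @export
mse <- function(x, max_scale = 20L, m = 2L, r = 0.2, tol = NULL) {
  if (inherits(x, "beat_intervals")) x <- accepted(x)
  x <- as.numeric(x)
  stopifnot(max_scale >= 1L, length(x) > (m + 1L) * max_scale)
  tol <- tol %||% (r * stats::sd(x))
  ent <- vapply(seq_len(max_scale), function(tau) {
    nb <- length(x) %/% tau
    cg <- if (tau == 1L) x else
      colMeans(matrix(x[seq_len(nb * tau)], nrow = tau))
    if (length(cg) <= m + 1L) return(NaN)
    as.numeric(sample_entropy(cg, m = m, tol = tol))
  }, numeric(1))
  structure(data.frame(scale = seq_len(max_scale), sampen = ent),
            class = c("mse_curve", "data.frame"), m = m, r = r, tol = tol)
}

#' @export
plot.mse_curve <- function(x, ...) {
  graphics::plot(x$scale, x$sampen, type = "b", xlab = "scale",
                 ylab = "sample entropy", ...)
  invisible(x)
}

#' Detrended fluctuation analysis (DFA)
#'
#' Integrates the mean-removed series, splits the profile into non-overlapping
#' boxes of `n` samples (trailing partial box dropped), removes a least-squares
#' linear trend per box, and reports the RMS residual `F(n)`.  By construction
#' `F(1) = F(2) = 0` (a line fits one or two points exactly).  Scaling
#' exponents are least-squares slopes of `log10 F` vs `log10 n`:
#' `alpha1` over scales 4-15 (short-term) and `alpha2` over 16-64
#' (long-term); the base level is `log10 F(4)`, the smallest usable scale.
#' White noise gives a slope of 0.5, pink noise 1.0, Brownian noise 1.5.
#'
#' @param x numeric series (or a [beat_intervals], whose accepted intervals
#'   are used).
#' @param scales integer box sizes; the default is a log-spaced set over
#'   4-64.  Scales with fewer than 2 complete boxes are dropped.
#' @return A data frame of class `"dfa_curve"` with columns `scale`,
#'   `fluctuation`; attributes `alpha1`, `alpha2`, `base_level`.
#' @seealso [dfa_fit()] for a slope over an arbitrary scale range.
#' @export
dfa <- function(x, scales = dfa_default_scales()) {
  if (inherits(x, "beat_intervals")) x <- accepted(x)
  x <- as.numeric(x)
  scales <- sort(unique(as.integer(scales)))
  if (length(x) < 2L * max(scales))
    warning("series shorter than twice the largest scale")
  y <- cumsum(x - mean(x))
  n <- length(y)
  fl <- vapply(scales, function(s) {
    nb <- n %/% s
    if (nb < 2L) return(NA_real_)
    if (s <= 2L) return(0)  # a line interpolates 1 or 2 points exactly
    m <- matrix(y[seq_len(nb * s)], nrow = s)
    tt <- seq_len(s)
    X <- cbind(1, tt)
    res <- m - X %*% solve(crossprod(X), crossprod(X, m))
    sqrt(mean(res^2))
  }, numeric(1))
  ok <- !is.na(fl)
  curve <- data.frame(scale = scales[ok], fluctuation = fl[ok])
  structure(curve,
            class = c("dfa_curve", "data.frame"),
            alpha1 = dfa_fit(curve, c(4, 15)),
            alpha2 = dfa_fit(curve, c(16, 64)),
            base_level = if (4 %in% curve$scale)
              log10(curve$fluctuation[curve$scale == 4]) else NA_real_)
}

dfa_default_scales <- function() {
  unique(round(2^seq(2, 6, by = 0.25)))
}

#' Fit a DFA scaling exponent over a scale range
#'
#' @param curve a `"dfa_curve"` from [dfa()] (or any data frame with `scale`
#'   and `fluctuation` columns).
#' @param range `[low, high]` inclusive scale range for the log-log fit.
#' @return Least-squares slope of `log10 F` vs `log10 n`; `NA` with fewer
#'   than 2 usable scales.
#' @export
dfa_fit <- function(curve, range = c(4, 64)) {
  sel <- curve$scale >= range[1L] & curve$scale <= range[2L] &
    curve$fluctuation > 0
  if (sum(sel) < 2L) return(NA_real_)
  unname(stats::coef(stats::lm(
    log10(curve$fluctuation[sel]) ~ log10(curve$scale[sel])))[2L])
}

#' @export
plot.dfa_curve <- function(x, ...) {
  graphics::plot(x$scale, x$fluctuation, type = "b", log = "xy",
                 xlab = "scale n", ylab = "F(n)", ...)
  invisible(x)
}
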