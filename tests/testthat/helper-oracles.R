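# Independent reference implementations used only to verify the package's
# fast paths; kept deliberately naive.

# Brute-force O(n^2) sample-entropy match counter (Chebyshev distance,
# self-matches excluded): returns c(B, A).
naive_sampen_counts <- function(x, m, tol) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1L)) {
    for (j in seq.int(i + 1L, nt)) {
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) <= tol) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= tol) A <- A + 1
      }
    }
  }
  c(B, A)
}

# Brute-force transient cut locator: first beat whose forward sliding-window
# mean is within tol of the steady-state level.
naive_transient_cut <- function(times, intervals, window, skip, tol) {
  thr <- mean(intervals[times - times[1] >= skip])
  for (i in seq_along(intervals)) {
    sel <- times >= times[i] & times < times[i] + window
    if (abs(mean(intervals[sel]) - thr) <= tol * thr) return(i)
  }
  NA_integer_
}

# A mildly structured positive interval fixture.
fixture_rr <- function(n = 512, seed = 1, base = 0.8, sd = 0.04) {
  gen_noise("white", n, mean = base, sd = sd, seed = seed)
}
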