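# Independent oracles used across the test files.  These deliberately do
# not share code with the package implementation.

# Direct O(n^2)-style correlation estimate with symmetric normalization:
# for each lag k, mean(x[t] y[t+k]) over the overlap divided by the
# product of the overlap-window means, minus 1.
direct_correlation <- function(x, y, lags) {
  n <- length(x)
  vapply(lags, function(k) {
    i <- seq_len(n - k)
    num <- mean(x[i] * y[i + k])
    num / (mean(x[i]) * mean(y[i + k])) - 1
  }, 1)
}

# Exhaustive enumeration of all perfect pairings of a label vector
# (TRUE = green), returning the expected fraction of mixed pairs.
# Independent recursion from the package's: walks every pairing and
# averages the per-pairing mixed fraction.
oracle_mixed_fraction <- function(M, N) {
  labels <- c(rep(TRUE, M), rep(FALSE, N))
  n_pairs <- length(labels) / 2
  fracs <- c()
  recurse <- function(lab, mixed) {
    if (length(lab) == 0) {
      fracs <<- c(fracs, mixed / n_pairs)
      return(invisible())
    }
    for (j in 2:length(lab))
      recurse(lab[-c(1, j)], mixed + (lab[1] != lab[j]))
  }
  recurse(labels, 0)
  mean(fracs)
}

# Quick single-segment trace splitter used by several tests.
split_trace <- function(trace, seg_s) {
  bins <- round(seg_s / trace$dt)
  n <- floor(length(trace$counts_green) / bins)
  lapply(seq_len(n), function(i) {
    idx <- ((i - 1) * bins + 1):(i * bins)
    structure(list(dt = trace$dt, duration = seg_s,
                   time = trace$time[idx],
                   counts_green = trace$counts_green[idx],
                   counts_red = trace$counts_red[idx]),
              class = "intensity_trace")
  })
}

default_geom <- function(r0 = 0) detection_geometry(222, 272, r0)
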