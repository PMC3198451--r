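# Independent oracles: deliberately naive implementations, kept separate
# from the package's code paths.

# Brute-force Monte-Carlo oracle for the RTW staircase equilibrium:
# stationary Gaussian RTs around the target, total-width window, plain
# loop. Returns the on-time fraction over the second half of the run.
staircaseOracleAccuracy <- function(stepError, stepCorrect, rtSd,
                                    nTrials = 50000L, initWidth = 200,
                                    minWidth = 20, seed = 1L) {
  set.seed(seed)
  width <- initWidth
  hits <- logical(nTrials)
  for (i in seq_len(nTrials)) {
    rt <- 1000 + rnorm(1, 0, rtSd)
    ok <- abs(rt - 1000) <= width / 2
    hits[i] <- ok
    width <- if (ok) max(width - stepCorrect, minWidth)
             else width + stepError
  }
  mean(hits[(nTrials %/% 2):nTrials])
}

# Exhaustive-scan oracle for the most negative deflection: plain loop over
# samples; post-event window, endpoints inclusive, 0 ms excluded, ties to
# the earliest sample.
minScanOracle <- function(values, times, window) {
  best <- Inf; lat <- NA_real_
  for (i in seq_along(times)) {
    t <- times[i]
    if (t <= 0 || t < window[1] || t > window[2]) next
    if (values[i] < best) { best <- values[i]; lat <- t }
  }
  list(amplitude = best, latency = lat)
}

# Exhaustive double-scan oracle for trough-to-peak: all trough candidates
# x all preceding maxima.
troughToPeakOracle <- function(values, times, troughWindow,
                               searchFrom = 0) {
  tr <- minScanOracle(values, times, troughWindow)
  peak <- -Inf
  for (i in seq_along(times)) {
    t <- times[i]
    if (t <= 0 || t <= searchFrom || t > tr$latency) next
    if (values[i] > peak) peak <- values[i]
  }
  list(amplitude = tr$amplitude - peak, latency = tr$latency)
}

# Random smooth test waves on the standard epoch axis.
randomWave <- function(times, roughness = 5) {
  raw <- cumsum(rnorm(length(times)))
  stats::filter(raw, rep(1 / roughness, roughness), circular = TRUE) |>
    as.numeric()
}
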