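# Independent oracles and fixture builders used across the suite.

# Exhaustive single-change-point likelihood scan over a count vector, written
# directly in terms of Poisson log-densities (independent of the package's
# profile-likelihood shortcut). Returns the 0-based change point maximizing
# the split likelihood, the split log-likelihood and the no-change
# log-likelihood.
oracleBestSplit <- function(x, minSeg = 2L) {
  n <- length(x)
  bestK <- NA_integer_
  bestLL <- -Inf
  for (k in minSeg:(n - minSeg)) {
    l <- x[1:k]
    r <- x[(k + 1):n]
    ll <- sum(dpois(l, mean(l), log = TRUE)) +
      sum(dpois(r, mean(r), log = TRUE))
    if (ll > bestLL + 1e-12) {
      bestLL <- ll
      bestK <- k
    }
  }
  list(k = bestK, splitLL = bestLL,
       nullLL = sum(dpois(x, mean(x), log = TRUE)))
}

# Brute-force renewal simulation: alternating lognormal(log10) on/off
# intervals until the window is filled; returns the number of on intervals.
oracleRenewalOnCount <- function(muOn, sdOn, muOff, sdOff, window,
                                 startOn) {
  total <- 0
  on <- startOn
  nOn <- 0L
  while (total < window) {
    d <- 10^rnorm(1, if (on) muOn else muOff, if (on) sdOn else sdOff)
    if (on) nOn <- nOn + 1L
    total <- total + d
    on <- !on
  }
  nOn
}

# Hand-build a labelled Segmentation from per-segment lengths (bins), exact
# segment means, level ids and level means. Counts are synthesized to be
# consistent in total (they are only used by noise estimation, which these
# tests bypass by passing noiseRms explicitly or not at all).
makeSegmentation <- function(lengths, means, levelIds, levelMeans,
                             onLevels = logical(0), binTime = 0.01,
                             nIntensities = length(levelMeans)) {
  counts <- as.integer(round(rep(means, lengths)))
  cps <- cumsum(lengths)
  cps <- cps[-length(cps)]
  new("Segmentation", counts = counts, binTime = binTime,
      changePoints = as.integer(cps),
      segmentLengths = as.integer(lengths),
      segmentMeans = as.numeric(means),
      levelIds = as.integer(levelIds),
      levelMeans = as.numeric(levelMeans),
      nIntensities = as.integer(nIntensities),
      onLevels = onLevels,
      noiseRms = if (length(onLevels)) 1 else NA_real_)
}

# Shared small critical-value table (built once per test run).
sharedCritTable <- local({
  tab <- NULL
  function() {
    if (is.null(tab))
      tab <<- estimateCriticalValues(c(16, 64, 256, 1000, 4000),
                                     alpha = 0.05, nReplicates = 800,
                                     rate = 5, seed = 42)
    tab
  }
})

# Ten plausible blinking-statistic means/sds for feature-space simulation.
refStatMeans <- c(5, 2.6, 8, 2.9, 0.8, 1.2, 1.2, 1.2, 10, 10)
refStatSds <- c(2, 1, 3, 1.5, 0.5, 0.8, 0.8, 0.8, 5, 5)
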