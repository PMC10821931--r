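#' @include AllClasses.R
NULL

# Two-rate Poisson generalized log-likelihood-ratio statistics for every
# admissible split of a count region. Returns 2 * (splitLL - nullLL) for
# splits k = minSeg .. n - minSeg (first part = bins 1..k), or NULL when the
# region is too short to split.
glrSplitStats <- function(x, minSeg = 2L) {
  n <- length(x)
  if (n < 2L * minSeg) return(NULL)
  S <- cumsum(as.numeric(x))
  Tt <- S[n]
  k <- minSeg:(n - minSeg)
  S1 <- S[k]
  S2 <- Tt - S1
  stat <- 2 * (xlogx(S1, k) + xlogx(S2, n - k) -
                 xlogx(Tt, n))
  list(k = k, stat = stat)
}

#' Monte-Carlo critical values for change-point detection
#'
#' For each region size in `nBinsGrid`, simulates constant-rate Poisson traces
#' and records the (1 - alpha) quantile of the maximal two-rate generalized
#' log-likelihood-ratio statistic. These critical values control the per-region
#' false-positive rate of [detectChangePoints()] at approximately `alpha`.
#'
#' @param nBinsGrid strictly increasing region sizes to tabulate.
#' @param alpha significance level in (0, 1).
#' @param nReplicates Monte-Carlo replicates per grid point (>= 100).
#' @param rate reference constant Poisson rate in counts/bin. The null
#'   quantile depends only weakly on the rate once it exceeds ~1 count/bin;
#'   the value used is recorded in the table metadata.
#' @param seed integer seed.
#' @param minSeg minimum segment length in bins.
#' @return A [CriticalValueTable-class].
#' @examples
#' tab <- estimateCriticalValues(c(50, 100), alpha = 0.05,
#'                               nReplicates = 200, seed = 1)
#' tab
#' @export
estimateCriticalValues <- function(nBinsGrid, alpha = 0.05,
                                   nReplicates = 1000, rate = 5,
                                   seed = 1, minSeg = 2L) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  if (nReplicates < 100) stop("'nReplicates' must be >= 100")
  nBinsGrid <- sort(unique(as.integer(nBinsGrid)))
  set.seed(as.integer(seed))
  crit <- vapply(nBinsGrid, function(n) {
    maxima <- vapply(seq_len(nReplicates), function(r) {
      g <- glrSplitStats(rpois(n, rate), minSeg)
      if (is.null(g)) 0 else max(g$stat)
    }, numeric(1))
    as.numeric(quantile(maxima, 1 - alpha, names = FALSE))
  }, numeric(1))
  new("CriticalValueTable", nBins = nBinsGrid, critValues = crit,
      alpha = alpha, nReplicates = as.integer(nReplicates),
      rate = rate, seed = as.integer(seed))
}

#' Interpolate a critical value for a region size
#'
#' Linear interpolation in log(bin count); clamped at the grid ends.
#'
#' @param table a [CriticalValueTable-class].
#' @param n region size in bins.
#' @return Critical value of the 2*log-GLR statistic.
#' @export
criticalValue <- function(table, n) {
  if (length(table@nBins) == 1L) return(table@critValues)
  approx(log(table@nBins), table@critValues, xout = log(n),
         rule = 2)$y
}

#' Detect intensity change points in a binned trace
#'
#' Recursive bisection with a generalized likelihood-ratio test under a
#' per-bin Poisson model: within each working region the split maximizing the
#' two-rate profile log-likelihood is accepted as a change point when its
#' statistic exceeds the Monte-Carlo critical value for that region's size,
#' and detection recurses on both sides. Ties in the maximal statistic are
#' broken toward the smallest bin index; candidate change points closer than
#' `minSeg` bins to a region boundary are not considered (the two-rate MLE is
#' undefined on an empty side).
#'
#' @param trace a [BlinkingTrace-class].
#' @param table a [CriticalValueTable-class]; when `NULL` a table is estimated
#'   on a log-spaced grid covering the trace length (500 replicates, seeded
#'   from `tableSeed`).
#' @param minSeg minimum segment length in bins (>= 2).
#' @param tableSeed seed for the on-the-fly table when `table` is `NULL`.
#' @return A [Segmentation-class] without level grouping (each segment is its
#'   own level).
#' @examples
#' tab <- estimateCriticalValues(c(64, 256, 1000), nReplicates = 200, seed = 1)
#' x <- c(rpois(500, 1), rpois(500, 20))
#' seg <- detectChangePoints(BlinkingTrace(x), tab)
#' changePoints(seg)
#' @export
detectChangePoints <- function(trace, table = NULL, minSeg = 2L,
                               tableSeed = 1) {
  x <- counts(trace)
  n <- length(x)
  if (n < 1L) stop("trace must be non-empty")
  if (is.null(table)) {
    grid <- unique(pmin(n, round(exp(seq(log(max(4 * minSeg, 8)),
                                         log(max(n, 9)), length.out = 6)))))
    grid <- grid[grid >= 2L * minSeg]
    table <- estimateCriticalValues(grid, nReplicates = 500,
                                    rate = max(mean(x), 0.5),
                                    seed = tableSeed)
  }

  cps <- integer(0)
  recurse <- function(lo, hi) {    # 1-based inclusive region bounds
    g <- glrSplitStats(x[lo:hi], minSeg)
    if (is.null(g)) return(invisible())
    best <- which.max(g$stat)      # first index wins ties
    if (g$stat[best] > criticalValue(table, hi - lo + 1L)) {
      k <- g$k[best]               # last bin of the left part, region-local
      cp <- lo + k - 1L            # global 1-based last bin of left segment
      cps <<- c(cps, cp)           # 0-based first bin of new segment == cp
      recurse(lo, cp)
      recurse(cp + 1L, hi)
    }
    invisible()
  }
  recurse(1L, n)
  cps <- sort(unique(cps))

  bounds <- c(0L, cps, n)
  lens <- diff(bounds)
  sums <- vapply(seq_along(lens), function(i)
    sum(x[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  means <- sums / lens
  new("Segmentation", counts = x, binTime = binTime(trace),
      changePoints = as.integer(cps), segmentLengths = as.integer(lens),
      segmentMeans = means,
      levelIds = as.integer(rank(means, ties.method = "first")),
      levelMeans = sort(means))
}

# Poisson profile log-likelihood contribution of a level (up to terms that
# cancel between groupings): S * log(S / L).
levelLL <- function(S, L) if (S > 0) S * log(S / L) else 0

#' Group segments into distinct intensity levels
#'
#' Agglomerative merging of segment intensities: starting from one level per
#' segment (ordered by mean), the pair of intensity-adjacent levels whose
#' merge costs the least profile log-likelihood is merged while the BIC of
#' the merged Poisson model is at least as good (i.e. while twice the
#' log-likelihood drop does not exceed log(nBins), the penalty for one rate
#' parameter). The resulting number of distinct levels is the N_I statistic.
#'
#' @param seg a [Segmentation-class] from [detectChangePoints()].
#' @return The segmentation with `levelIds`, `levelMeans` and `nIntensities`
#'   filled in.
#' @export
groupLevels <- function(seg) {
  lens <- as.numeric(seg@segmentLengths)
  sums <- seg@segmentMeans * lens
  nBinsTot <- length(seg@counts)
  penalty <- log(nBinsTot)

  # levels as a per-segment assignment; start with one level per segment
  lvl <- seq_along(lens)
  repeat {
    S <- tapply(sums, lvl, sum)
    L <- tapply(lens, lvl, sum)
    ids <- as.integer(names(S))
    ord <- order(S / L)
    if (length(ord) < 2L) break
    # candidate merges between intensity-adjacent levels
    delta <- vapply(seq_len(length(ord) - 1L), function(i) {
      a <- ord[i]; b <- ord[i + 1L]
      2 * (levelLL(S[a], L[a]) + levelLL(S[b], L[b]) -
             levelLL(S[a] + S[b], L[a] + L[b]))
    }, numeric(1))
    best <- which.min(delta)
    if (delta[best] > penalty) break
    keep <- ids[ord[best]]
    drop <- ids[ord[best + 1L]]
    lvl[lvl == drop] <- keep
  }

  S <- tapply(sums, lvl, sum)
  L <- tapply(lens, lvl, sum)
  means <- as.numeric(S / L)
  ord <- order(means)
  newId <- match(lvl, as.integer(names(S))[ord])
  seg@levelIds <- as.integer(newId)
  seg@levelMeans <- means[ord]
  seg@nIntensities <- length(means)
  seg
}

#' Label intensity levels on/off
#'
#' The lowest-intensity level is denoted off; a level is on when its mean
#' exceeds the off mean by more than one standard deviation of the rms noise.
#' Levels failing the criterion are merged into off (their segments
#' relabelled and the off mean re-pooled). By default the rms noise is
#' estimated as the standard deviation of the counts in bins assigned to the
#' lowest level.
#'
#' @param seg a grouped [Segmentation-class] (see [groupLevels()]).
#' @param noiseRms fixed rms noise in counts/bin, or `NULL` to estimate from
#'   the lowest-level bins.
#' @return The segmentation with `onLevels` and `noiseRms` filled in. The
#'   `nIntensities` (N_I) value from grouping is preserved.
#' @export
labelOnOff <- function(seg, noiseRms = NULL) {
  if (is.na(seg@nIntensities))
    stop("segmentation must be grouped first (see groupLevels())")
  binLevel <- rep(seg@levelIds, seg@segmentLengths)
  if (is.null(noiseRms)) {
    offBins <- seg@counts[binLevel == 1L]
    noiseRms <- if (length(offBins) >= 2L) sd(offBins)
      else sqrt(max(mean(seg@counts), 1e-9))
    if (!is.finite(noiseRms)) noiseRms <- 0
  }
  if (noiseRms < 0) stop("noiseRms must be >= 0")

  repeat {
    if (length(seg@levelMeans) == 1L) break
    offMean <- seg@levelMeans[1L]
    fail <- which(seg@levelMeans <= offMean + noiseRms)[-1L]
    if (!length(fail)) break
    # merge failing levels into off and re-pool
    lvl <- seg@levelIds
    lvl[lvl %in% fail] <- 1L
    lvl <- match(lvl, sort(unique(lvl)))
    lens <- as.numeric(seg@segmentLengths)
    sums <- seg@segmentMeans * lens
    S <- tapply(sums, lvl, sum)
    L <- tapply(lens, lvl, sum)
    seg@levelIds <- as.integer(lvl)
    seg@levelMeans <- as.numeric(S / L)
  }
  seg@onLevels <- c(FALSE, rep(TRUE, length(seg@levelMeans) - 1L))
  seg@noiseRms <- noiseRms
  seg
}

#' Run the full change-point stage on one trace
#'
#' Convenience chain: [detectChangePoints()], [groupLevels()],
#' [labelOnOff()].
#'
#' @inheritParams detectChangePoints
#' @param noiseRms see [labelOnOff()].
#' @return A labelled [Segmentation-class].
#' @export
segmentTrace <- function(trace, table = NULL, minSeg = 2L,
                         noiseRms = NULL, tableSeed = 1) {
  seg <- detectChangePoints(trace, table, minSeg = minSeg,
                            tableSeed = tableSeed)
  labelOnOff(groupLevels(seg), noiseRms = noiseRms)
}

#' Serialize a segmentation to a delimited table
#'
#' One row per segment: index, half-open 0-based bin range, mean counts,
#' level id and on/off flag.
#'
#' @param seg a labelled [Segmentation-class].
#' @return data.frame with columns `segment`, `start_bin`, `end_bin`,
#'   `mean_counts`, `level`, `on`.
#' @export
segmentationTable <- function(seg) {
  bounds <- c(0L, seg@changePoints, length(seg@counts))
  on <- if (length(seg@onLevels)) seg@onLevels[seg@levelIds]
        else rep(NA, length(seg@segmentLengths))
  data.frame(segment = seq_along(seg@segmentLengths),
             start_bin = head(bounds, -1L),
             end_bin = tail(bounds, -1L),
             mean_counts = seg@segmentMeans,
             level = seg@levelIds,
             on = on)
}
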