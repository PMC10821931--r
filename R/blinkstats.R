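#' @include AllClasses.R
NULL

#' Truncate a trace to an analysis window
#'
#' Keeps the first `floor(windowS / binTime)` bins. Used to put traces
#' acquired over different experimental windows on a common footing (e.g.
#' truncating 150-s traces to 100 s before comparison with a class measured
#' over 100 s).
#'
#' @param trace a [BlinkingTrace-class].
#' @param windowS analysis window in seconds (> 0).
#' @return The truncated trace; if the window is at least the trace duration
#'   the trace is returned unchanged with a warning.
#' @examples
#' tr <- BlinkingTrace(rpois(15000, 5), binTime = 0.01)
#' length(counts(truncateTrace(tr, 100)))   # 10000
#' @export
truncateTrace <- function(trace, windowS) {
  stopifnot_scalar(windowS, "windowS", positive = TRUE)
  nKeep <- floor(windowS / binTime(trace) + 1e-9)
  if (nKeep >= length(counts(trace))) {
    if (nKeep > length(counts(trace)))
      warning("window exceeds trace duration; trace returned unchanged")
    return(trace)
  }
  initialize(trace, counts = counts(trace)[seq_len(nKeep)])
}

#' Build the segment/interval event table
#'
#' Converts a labelled segmentation into the blinking event taxonomy: every
#' segment (one constant intensity) is assigned to an interval, where an
#' interval is a maximal run of consecutive same-state segments; the first
#' and last intervals are flagged as window-censored because their true
#' durations extend beyond the acquisition window.
#'
#' @param seg a labelled [Segmentation-class] (see [labelOnOff()]).
#' @return An [EventTable-class].
#' @export
buildEventTable <- function(seg) {
  if (!length(seg@onLevels))
    stop("segmentation must be on/off labelled first (see labelOnOff())")
  bt <- seg@binTime
  nSeg <- length(seg@segmentLengths)
  on <- seg@onLevels[seg@levelIds]
  bounds <- c(0L, seg@changePoints, length(seg@counts))
  start_s <- head(bounds, -1L) * bt
  end_s <- tail(bounds, -1L) * bt
  runs <- rle(on)
  intervalId <- rep(seq_along(runs$lengths), runs$lengths)
  nInt <- length(runs$lengths)
  segCensored <- intervalId == 1L | intervalId == nInt
  segmentsDf <- data.frame(
    segment = seq_len(nSeg),
    start_s = start_s, end_s = end_s,
    duration_s = end_s - start_s,
    intensity = seg@levelMeans[seg@levelIds],
    on = on,
    interval = intervalId,
    censored = segCensored)
  intervalsDf <- data.frame(
    interval = seq_len(nInt),
    state = ifelse(runs$values, "on", "off"),
    duration_s = as.numeric(tapply(segmentsDf$duration_s, intervalId, sum)),
    n_segments = runs$lengths,
    censored = seq_len(nInt) %in% c(1L, nInt))
  new("EventTable", segments = segmentsDf, intervals = intervalsDf,
      binTime = bt)
}

#' Compute the ten blinking statistics of one molecule
#'
#' From the event taxonomy of a trace: the number of distinct intensities
#' N_I (including off), the minimum and maximum emissive (on) intensities,
#' the duration-weighted time-averaged intensity over the whole trace, the
#' mean on/off segment and interval durations, and the on/off segment counts.
#' Window-censored boundary events are included in these per-trace counts and
#' averages (they are excluded from duration-distribution fitting instead;
#' see [poolDurations()]). Statistics with empty support (e.g. no on event)
#' are set to 0 and flagged.
#'
#' @param events an [EventTable-class].
#' @param seg the matching labelled [Segmentation-class] (provides N_I).
#' @param includeCensored include window-censored boundary events in the
#'   duration averages (default `TRUE`).
#' @return One-row data.frame with the ten statistics in [statNames()] order
#'   plus logical `flag_no_on` and `flag_no_off` degeneracy flags.
#' @export
computeStatVector <- function(events, seg, includeCensored = TRUE) {
  s <- events@segments
  iv <- events@intervals
  if (!nrow(s)) stop("event table is empty")
  onMeans <- seg@levelMeans[which(seg@onLevels)]
  noOn <- !any(s$on)
  noOff <- all(s$on)

  avgOr0 <- function(x) if (length(x)) mean(x) else 0
  segKeep <- if (includeCensored) rep(TRUE, nrow(s)) else !s$censored
  intKeep <- if (includeCensored) rep(TRUE, nrow(iv)) else !iv$censored

  out <- data.frame(
    N_I = if (!is.na(seg@nIntensities)) seg@nIntensities
          else length(seg@levelMeans),
    I_min = if (noOn) 0 else min(onMeans),
    I_max = if (noOn) 0 else max(onMeans),
    I_t_avg = sum(s$duration_s * s$intensity) / sum(s$duration_s),
    t_on_seg = avgOr0(s$duration_s[segKeep & s$on]),
    t_off_seg = avgOr0(s$duration_s[segKeep & !s$on]),
    t_on_int = avgOr0(iv$duration_s[intKeep & iv$state == "on"]),
    t_off_int = avgOr0(iv$duration_s[intKeep & iv$state == "off"]),
    N_on_seg = sum(s$on),
    N_off_seg = sum(!s$on),
    flag_no_on = noOn,
    flag_no_off = noOff)
  rownames(out) <- NULL
  out
}

#' Compute the blinking-statistic table of a population
#'
#' Runs the change-point stage ([segmentTrace()]) and statistic extraction on
#' every trace of a population.
#'
#' @param population list of [BlinkingTrace-class] objects.
#' @param table a [CriticalValueTable-class] shared across traces; when
#'   `NULL` one is estimated from the first trace's length.
#' @param truncationS optional common analysis window in seconds applied
#'   before detection (see [truncateTrace()]).
#' @param minSeg,noiseRms passed to [segmentTrace()].
#' @param tableSeed seed for an on-the-fly critical-value table.
#' @return data.frame with `molecule_id`, `class_label`, the ten statistics
#'   and the degeneracy flags; one row per molecule.
#' @export
computeStatTable <- function(population, table = NULL, truncationS = NULL,
                             minSeg = 2L, noiseRms = NULL, tableSeed = 1) {
  if (!length(population)) stop("empty population")
  if (!is.null(truncationS))
    population <- lapply(population, truncateTrace, windowS = truncationS)
  if (is.null(table)) {
    n <- length(counts(population[[1L]]))
    grid <- unique(round(exp(seq(log(8), log(max(n, 9)), length.out = 6))))
    table <- estimateCriticalValues(grid, nReplicates = 500,
                                    rate = max(mean(counts(population[[1L]])),
                                               0.5),
                                    seed = tableSeed)
  }
  rows <- lapply(population, function(tr) {
    seg <- segmentTrace(tr, table, minSeg = minSeg, noiseRms = noiseRms)
    ev <- buildEventTable(seg)
    cbind(data.frame(molecule_id = moleculeId(tr),
                     class_label = classLabel(tr),
                     stringsAsFactors = FALSE),
          computeStatVector(ev, seg))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pool event durations across molecules
#'
#' Collects on/off segment or interval durations from a list of event tables
#' for duration-distribution fitting. Window-censored boundary events are
#' excluded by default: their recorded durations are lower bounds truncated
#' by the acquisition window and would bias heavy-tail fits.
#'
#' @param eventTables list of [EventTable-class] objects.
#' @param state `"on"` or `"off"`.
#' @param kind `"interval"` (default) or `"segment"`.
#' @param includeCensored include window-censored boundary events.
#' @return Numeric vector of durations in seconds.
#' @export
poolDurations <- function(eventTables, state = c("on", "off"),
                          kind = c("interval", "segment"),
                          includeCensored = FALSE) {
  state <- match.arg(state)
  kind <- match.arg(kind)
  unlist(lapply(eventTables, function(ev) {
    if (kind == "interval") {
      iv <- ev@intervals
      keep <- iv$state == state & (includeCensored | !iv$censored)
      iv$duration_s[keep]
    } else {
      s <- ev@segments
      keep <- (s$on == (state == "on")) & (includeCensored | !s$censored)
      s$duration_s[keep]
    }
  }), use.names = FALSE)
}
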