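#' @include AllClasses.R
NULL

# Parameter validation shared by sampleDurations() and MechanismSpec validity.
validateFamilyParams <- function(family, params) {
  need <- function(nm) {
    v <- params[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || is.na(v))
      stop(sprintf("family '%s' requires numeric parameter '%s'", family, nm),
           call. = FALSE)
    v
  }
  switch(family,
    lognormal = {
      need("mu")
      if (need("sigma") <= 0) stop("lognormal 'sigma' must be > 0",
                                   call. = FALSE)
    },
    weibull = {
      if (need("shape") <= 0) stop("weibull 'shape' must be > 0",
                                   call. = FALSE)
      if (need("scale") <= 0) stop("weibull 'scale' must be > 0",
                                   call. = FALSE)
    },
    exponential = {
      if (need("rate") <= 0) stop("exponential 'rate' must be > 0",
                                  call. = FALSE)
    },
    power_law = {
      if (need("alpha") <= 1) stop("power-law 'alpha' must be > 1",
                                   call. = FALSE)
      if (need("xmin") <= 0) stop("power-law 'xmin' must be > 0",
                                  call. = FALSE)
    },
    truncated_power_law = {
      if (need("alpha") <= 1) stop("power-law 'alpha' must be > 1",
                                   call. = FALSE)
      if (need("xmin") <= 0) stop("power-law 'xmin' must be > 0",
                                  call. = FALSE)
      if (need("cutoffRate") < 0)
        stop("'cutoffRate' must be >= 0", call. = FALSE)
    },
    stop(sprintf("unknown duration family '%s'", family), call. = FALSE)
  )
  invisible(TRUE)
}

#' Sample blinking event durations from a mechanistic family
#'
#' Draws on/off event durations from the distribution families that the
#' blinking literature associates with specific photophysical mechanisms:
#' \describe{
#'   \item{`lognormal`}{dispersive electron transfer (Albery kinetics with
#'     normally distributed activation barriers); `mu` and `sigma` are the
#'     mean and sd of log10(duration / s), so `10^mu` is the median duration.}
#'   \item{`weibull`}{stretched-exponential survival
#'     \eqn{exp(-(t/scale)^{shape})}, associated with ESIPT photoprotection.}
#'   \item{`exponential`}{first-order (triplet) blinking; parameter `rate`
#'     in 1/s.}
#'   \item{`power_law` / `truncated_power_law`}{quantum-dot intermittency;
#'     density proportional to \eqn{t^{-alpha}} above `xmin`, optionally
#'     damped by \eqn{exp(-cutoffRate \cdot t)}. Pure power laws are sampled
#'     by inverse CDF, truncated ones by rejection against the exponential
#'     cutoff.}
#' }
#'
#' @param family family identifier (see above).
#' @param params named list of family parameters.
#' @param n number of durations (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @return Numeric vector of `n` strictly positive durations in seconds.
#' @examples
#' d <- sampleDurations("lognormal", list(mu = 0.01, sigma = 1.9), 1000,
#'                      seed = 1)
#' median(d)   # close to 10^0.01
#' @export
sampleDurations <- function(family, params, n, seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1")
  n <- as.integer(n)
  validateFamilyParams(family, params)
  if (!is.null(seed)) set.seed(as.integer(seed))
  switch(family,
    lognormal = 10^rnorm(n, params$mu, params$sigma),
    weibull = rweibull(n, shape = params$shape, scale = params$scale),
    exponential = rexp(n, rate = params$rate),
    power_law = params$xmin * (1 - runif(n))^(-1 / (params$alpha - 1)),
    truncated_power_law = {
      a <- params$alpha; xm <- params$xmin; lam <- params$cutoffRate
      out <- numeric(0)
      while (length(out) < n) {
        m <- max(2L * (n - length(out)), 64L)
        cand <- xm * (1 - runif(m))^(-1 / (a - 1))
        keep <- runif(m) < exp(-lam * (cand - xm))
        out <- c(out, cand[keep])
      }
      out[seq_len(n)]
    })
}

#' Construct a MechanismSpec
#'
#' @param classLabel class name attached to simulated traces.
#' @param onFamily,onParams,offFamily,offParams duration families and
#'   parameters for on and off intervals (see [sampleDurations()]).
#' @param levelCountProbs probabilities over 1, 2, ... emissive levels per
#'   molecule; defaults to a broad 1-7 level support reproducing non-binary
#'   traces.
#' @param levelRateMean,levelRateSd mean/sd of per-level emissive rates
#'   (counts/bin above background).
#' @param backgroundRate mean off-level counts/bin.
#' @param bleachMean mean exponential photobleach time (s); `Inf` disables.
#' @param startStatePOn probability the trace starts on.
#' @return A validated [MechanismSpec-class].
#' @export
mechanismSpec <- function(classLabel,
                          onFamily = "lognormal",
                          onParams = list(mu = 0.01, sigma = 1.9),
                          offFamily = "lognormal",
                          offParams = list(mu = -1.27, sigma = 2.07),
                          levelCountProbs = c(0.05, 0.1, 0.2, 0.25,
                                              0.2, 0.15, 0.05),
                          levelRateMean = 6, levelRateSd = 3,
                          backgroundRate = 0.2,
                          bleachMean = 25, startStatePOn = 0.5) {
  new("MechanismSpec", classLabel = as.character(classLabel),
      onFamily = onFamily, onParams = onParams,
      offFamily = offFamily, offParams = offParams,
      levelCountProbs = levelCountProbs / sum(levelCountProbs),
      levelRateMean = levelRateMean, levelRateSd = levelRateSd,
      backgroundRate = backgroundRate, bleachMean = bleachMean,
      startStatePOn = startStatePOn)
}

#' Preset mechanism specifications for the model emitters
#'
#' Ready-made [MechanismSpec-class] objects for the emitter classes studied in
#' blink-based multiplexing work: the xanthene (rhodamine) dyes 5ROX, R123,
#' R560, R6G and RB (dispersive-ET lognormal on/off intervals, single-step
#' photobleaching within tens of seconds), the BODIPY dye PM605 (lognormal),
#' the ESIPT anthraquinone AZ (lognormal on, Weibull off, enhanced
#' photostability) and core-shell quantum dots QD (truncated power laws, no
#' appreciable bleaching). Lognormal parameters are in log10 seconds. Where a
#' class's dispersion parameters are not individually established, values
#' representative of the class range are used (see the package vignette).
#'
#' @param name one of `"5ROX"`, `"R123"`, `"R560"`, `"R6G"`, `"RB"`,
#'   `"PM605"`, `"AZ"`, `"QD"`.
#' @return A [MechanismSpec-class].
#' @examples
#' presetSpec("R6G")
#' @export
presetSpec <- function(name) {
  rhodOn <- list(mu = 0.01, sigma = 1.9)
  switch(match.arg(name, c("5ROX", "R123", "R560", "R6G", "RB",
                           "PM605", "AZ", "QD")),
    "5ROX" = mechanismSpec("5ROX", onParams = rhodOn,
                           offParams = list(mu = -1.3, sigma = 2.0)),
    "R6G" = mechanismSpec("R6G", onParams = rhodOn,
                          offParams = list(mu = -1.27, sigma = 2.07)),
    "R560" = mechanismSpec("R560", onParams = rhodOn,
                           offParams = list(mu = -0.7, sigma = 2.2)),
    "RB" = mechanismSpec("RB", onParams = rhodOn,
                         offParams = list(mu = -0.3, sigma = 2.6)),
    "R123" = mechanismSpec("R123", onParams = rhodOn,
                           offParams = list(mu = -0.1, sigma = 2.4)),
    "PM605" = mechanismSpec("PM605",
                            onParams = list(mu = 0.3, sigma = 2.01),
                            offParams = list(mu = -0.7, sigma = 2.04)),
    "AZ" = mechanismSpec("AZ",
                         onParams = list(mu = 0.8, sigma = 1.6),
                         offFamily = "weibull",
                         offParams = list(shape = 0.5, scale = 0.5),
                         bleachMean = 70),
    "QD" = mechanismSpec("QD",
                         onFamily = "truncated_power_law",
                         onParams = list(alpha = 1.5, xmin = 0.01,
                                         cutoffRate = 0.1),
                         offFamily = "truncated_power_law",
                         offParams = list(alpha = 1.6, xmin = 0.01,
                                          cutoffRate = 0.02),
                         levelRateMean = 12, levelRateSd = 4,
                         bleachMean = Inf))
}

#' Construct an IntervalSequence by hand
#'
#' Builds the alternating on/off schedule directly from durations, for tests
#' and forward-model experiments that bypass [simulateMolecule()]. Each on
#' interval is one segment at the corresponding entry of `onRates` (recycled).
#'
#' @param durations positive interval durations in seconds, alternating state.
#' @param startOn logical; state of the first interval.
#' @param bleachTime photobleach time in seconds (`Inf` for none). Emission
#'   after `bleachTime` is forced off.
#' @param onRates emissive rates (counts/bin) assigned to on intervals.
#' @return An [IntervalSequence-class].
#' @export
intervalSequence <- function(durations, startOn = TRUE, bleachTime = Inf,
                             onRates = 5) {
  nInt <- length(durations)
  states <- if (startOn) rep(c("on", "off"), length.out = nInt)
            else rep(c("off", "on"), length.out = nInt)
  ends <- cumsum(durations)
  starts <- c(0, head(ends, -1L))
  onIdx <- which(states == "on")
  rates <- rep(NA_real_, nInt)
  if (length(onIdx))
    rates[onIdx] <- rep(onRates, length.out = length(onIdx))
  pieces <- data.frame(start = starts, end = ends, state = states,
                       rate = rates, stringsAsFactors = FALSE)
  pieces <- applyBleach(pieces, bleachTime)
  new("IntervalSequence", durations = durations, startOn = startOn,
      bleachTime = bleachTime, pieces = pieces)
}

# Force all emission after the bleach time off by clipping/splitting pieces.
applyBleach <- function(pieces, bleachTime) {
  if (!is.finite(bleachTime)) return(pieces)
  if (bleachTime <= 0) {
    if (!nrow(pieces)) return(pieces)
    return(data.frame(start = min(pieces$start), end = max(pieces$end),
                      state = "off", rate = NA_real_,
                      stringsAsFactors = FALSE))
  }
  keep <- pieces[pieces$start < bleachTime, , drop = FALSE]
  total <- max(pieces$end)
  if (nrow(keep)) {
    keep$end <- pmin(keep$end, bleachTime)
  }
  if (bleachTime < total) {
    keep <- rbind(keep, data.frame(start = bleachTime, end = total,
                                   state = "off", rate = NA_real_,
                                   stringsAsFactors = FALSE))
  }
  keep
}

#' Simulate one molecule's interval sequence
#'
#' Realizes the alternating on/off renewal process of a [MechanismSpec-class]
#' over an observation window: interval durations are drawn from the class's
#' on/off families until the window is covered; the molecule's emissive-level
#' set (count drawn from `levelCountProbs`, rates i.i.d. gamma above
#' background) is assigned to on segments, with on-on level switches at
#' segment boundaries drawn from the same on-duration family; an irreversible
#' photobleach time is drawn and all later emission is forced off.
#'
#' @param spec a [MechanismSpec-class].
#' @param window observation window in seconds (> 0).
#' @param seed optional integer seed.
#' @return An [IntervalSequence-class] whose `pieces` carry segment-level
#'   rates.
#' @export
simulateMolecule <- function(spec, window, seed = NULL) {
  stopifnot_scalar(window, "window", positive = TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  nLevels <- sample.int(length(spec@levelCountProbs), 1L,
                        prob = spec@levelCountProbs)
  rates <- if (spec@levelRateSd > 0) {
    shp <- (spec@levelRateMean / spec@levelRateSd)^2
    spec@backgroundRate +
      rgamma(nLevels, shape = shp, rate = shp / spec@levelRateMean)
  } else rep(spec@backgroundRate + spec@levelRateMean, nLevels)
  startOn <- runif(1) < spec@startStatePOn
  bleachTime <- if (!is.finite(spec@bleachMean)) Inf
    else if (spec@bleachMean == 0) 0
    else rexp(1, 1 / spec@bleachMean)

  durations <- numeric(0)
  states <- character(0)
  total <- 0
  on <- startOn
  while (total < window) {
    fam <- if (on) spec@onFamily else spec@offFamily
    par <- if (on) spec@onParams else spec@offParams
    d <- sampleDurations(fam, par, 1L)
    durations <- c(durations, d)
    states <- c(states, if (on) "on" else "off")
    total <- total + d
    on <- !on
  }

  # Expand on intervals into constant-rate segments (on-on switching).
  starts <- c(0, head(cumsum(durations), -1L))
  segs <- vector("list", length(durations))
  for (i in seq_along(durations)) {
    if (states[i] == "off") {
      segs[[i]] <- data.frame(start = starts[i],
                              end = starts[i] + durations[i],
                              state = "off", rate = NA_real_,
                              stringsAsFactors = FALSE)
    } else {
      remaining <- durations[i]
      t0 <- starts[i]
      sub <- list()
      while (remaining > 0) {
        d <- if (nLevels > 1L)
          min(sampleDurations(spec@onFamily, spec@onParams, 1L), remaining)
        else remaining
        lvl <- sample.int(nLevels, 1L)
        sub[[length(sub) + 1L]] <-
          data.frame(start = t0, end = t0 + d, state = "on",
                     rate = rates[lvl], stringsAsFactors = FALSE)
        t0 <- t0 + d
        remaining <- remaining - d
      }
      segs[[i]] <- do.call(rbind, sub)
    }
  }
  pieces <- do.call(rbind, segs)
  pieces <- applyBleach(pieces, bleachTime)
  new("IntervalSequence", durations = durations, startOn = startOn,
      bleachTime = bleachTime, pieces = pieces)
}

#' Render an interval sequence into a binned photon-count trace
#'
#' Forward model for acquisition: each bin's count is Poisson with mean equal
#' to the time-weighted average of the active emission rate over the bin (the
#' segment rate during on pieces, the background rate otherwise), so a bin
#' straddling a switch receives the duration-weighted mixture of both rates.
#' The generative ground truth (pieces and per-bin on-time fraction) is
#' stored on the trace.
#'
#' @param seq an [IntervalSequence-class].
#' @param backgroundRate mean off-state counts/bin (>= 0).
#' @param binTime bin width in seconds (> 0).
#' @param window trace duration in seconds (>= one bin).
#' @param moleculeId,classLabel metadata attached to the trace.
#' @param seed optional integer seed for the Poisson draw.
#' @return A [BlinkingTrace-class] with `floor(window / binTime)` bins.
#' @export
renderTrace <- function(seq, backgroundRate = 0.2, binTime = 0.01,
                        window = 150, moleculeId = "trace",
                        classLabel = NA_character_, seed = NULL) {
  stopifnot_scalar(binTime, "binTime", positive = TRUE)
  if (backgroundRate < 0) stop("backgroundRate must be >= 0")
  nBins <- floor(window / binTime + 1e-9)
  if (nBins < 1L) stop("window must cover at least one bin")
  if (!is.null(seed)) set.seed(as.integer(seed))

  mu <- rep(0, nBins)
  onTime <- rep(0, nBins)
  pieces <- seq@pieces
  for (i in seq_len(nrow(pieces))) {
    a <- max(0, pieces$start[i])
    b <- min(window, pieces$end[i])
    if (b <= a) next
    i0 <- floor(a / binTime + 1e-12) + 1L
    i1 <- min(ceiling(b / binTime - 1e-12), nBins)
    if (i1 < i0) next
    idx <- i0:i1
    ov <- pmin(b, idx * binTime) - pmax(a, (idx - 1) * binTime)
    rate <- if (pieces$state[i] == "on") pieces$rate[i] else backgroundRate
    mu[idx] <- mu[idx] + ov / binTime * rate
    if (pieces$state[i] == "on") onTime[idx] <- onTime[idx] + ov
  }
  # time not covered by any piece (sequence shorter than window) is off
  covered <- rep(0, nBins)
  for (i in seq_len(nrow(pieces))) {
    a <- max(0, pieces$start[i]); b <- min(window, pieces$end[i])
    if (b <= a) next
    i0 <- floor(a / binTime + 1e-12) + 1L
    i1 <- min(ceiling(b / binTime - 1e-12), nBins)
    if (i1 < i0) next
    idx <- i0:i1
    covered[idx] <- covered[idx] +
      (pmin(b, idx * binTime) - pmax(a, (idx - 1) * binTime))
  }
  mu <- mu + pmax(binTime - covered, 0) / binTime * backgroundRate

  BlinkingTrace(rpois(nBins, mu), binTime = binTime,
                moleculeId = moleculeId, classLabel = classLabel,
                groundTruth = list(pieces = pieces,
                                   onFraction = onTime / binTime,
                                   bleachTime = seq@bleachTime))
}

#' Simulate a labelled population of blinking traces
#'
#' Generates `nPerClass` traces per mechanism spec; every molecule's RNG
#' stream is derived deterministically from the master seed, so the same seed
#' reproduces the population bit for bit.
#'
#' @param specs list of [MechanismSpec-class] objects (one per class).
#' @param nPerClass molecules per class (>= 1).
#' @param window trace duration in seconds.
#' @param binTime bin width in seconds.
#' @param seed master integer seed.
#' @return A list of [BlinkingTrace-class] objects, names
#'   `<classLabel>_<index>`.
#' @examples
#' pop <- simulatePopulation(list(presetSpec("R6G"), presetSpec("AZ")),
#'                           nPerClass = 2, window = 5, seed = 7)
#' vapply(pop, classLabel, character(1))
#' @export
simulatePopulation <- function(specs, nPerClass, window = 150,
                               binTime = 0.01, seed = 1) {
  if (!length(specs)) stop("'specs' must contain at least one MechanismSpec")
  if (nPerClass < 1) stop("'nPerClass' must be >= 1")
  out <- list()
  idx <- 0L
  for (spec in specs) {
    for (i in seq_len(nPerClass)) {
      idx <- idx + 1L
      sq <- simulateMolecule(spec, window, seed = deriveSeed(seed, idx, 1L))
      id <- sprintf("%s_%03d", spec@classLabel, i)
      out[[id]] <- renderTrace(sq, backgroundRate = spec@backgroundRate,
                               binTime = binTime, window = window,
                               moleculeId = id,
                               classLabel = spec@classLabel,
                               seed = deriveSeed(seed, idx, 2L))
    }
  }
  out
}

#' Simulate blinking-statistic vectors directly in feature space
#'
#' Draws the ten per-molecule blinking statistics from independent normal
#' distributions per class, bypassing trace simulation and change-point
#' detection. This is the generator used for classifier calibration (e.g.
#' identical classes should give chance-level cross-validated accuracy).
#'
#' @param classMeans named list (or matrix with one row per class) of
#'   length-10 mean vectors in [statNames()] order.
#' @param classSds matching per-statistic standard deviations (>= 0).
#' @param nPerClass molecules per class.
#' @param seed integer seed.
#' @return data.frame with `molecule_id`, `class_label` and the ten
#'   statistics.
#' @examples
#' m <- c(5, 2.6, 8, 2.9, 0.8, 1.2, 1.2, 1.2, 10, 10)
#' s <- rep(1, 10)
#' x <- simulateStatVectors(list(A = m, B = m), list(A = s, B = s),
#'                          nPerClass = 20, seed = 1)
#' table(x$class_label)
#' @export
simulateStatVectors <- function(classMeans, classSds, nPerClass, seed = 1) {
  if (is.matrix(classMeans))
    classMeans <- split(classMeans, seq_len(nrow(classMeans)))
  if (is.matrix(classSds))
    classSds <- split(classSds, seq_len(nrow(classSds)))
  if (length(classMeans) != length(classSds))
    stop("classMeans and classSds must describe the same classes")
  labels <- names(classMeans) %||% paste0("class", seq_along(classMeans))
  set.seed(as.integer(seed))
  rows <- list()
  for (k in seq_along(classMeans)) {
    mu <- as.numeric(classMeans[[k]])
    sdv <- as.numeric(classSds[[k]])
    if (length(mu) != 10L || length(sdv) != 10L)
      stop("each class needs 10 means and 10 sds (one per statistic)")
    if (any(sdv < 0)) stop("sds must be >= 0")
    X <- matrix(rnorm(nPerClass * 10L, rep(mu, each = nPerClass),
                      rep(sdv, each = nPerClass)),
                nrow = nPerClass)
    colnames(X) <- statNames()
    rows[[k]] <- data.frame(
      molecule_id = sprintf("%s_%03d", labels[k], seq_len(nPerClass)),
      class_label = labels[k], X,
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
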