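#' @include utils.R
NULL

.DURATION_FAMILIES <- c("lognormal", "weibull", "exponential",
                        "power_law", "truncated_power_law")

# ---------------------------------------------------------------------------
# MechanismSpec: the generative model of one emitter class
# ---------------------------------------------------------------------------

#' Mechanistic blinking specification for one emitter class
#'
#' Describes the stochastic model from which blinking traces of one class are
#' simulated: the on- and off-interval duration families (lognormal in log10
#' seconds for dispersive electron-transfer kinetics, Weibull for ESIPT
#' photophysics, truncated power law for quantum dots, exponential for
#' first-order triplet blinking), the number and brightness of emissive
#' intensity levels, the background count rate, photobleaching, and the
#' initial state.
#'
#' @slot classLabel class name attached to simulated traces.
#' @slot onFamily,offFamily duration family identifiers; one of
#'   `"lognormal"`, `"weibull"`, `"exponential"`, `"power_law"`,
#'   `"truncated_power_law"`.
#' @slot onParams,offParams named lists of family parameters (see
#'   [sampleDurations()]).
#' @slot levelCountProbs probabilities over 1, 2, ... emissive levels per
#'   molecule.
#' @slot levelRateMean,levelRateSd mean and sd of the per-level emissive count
#'   rate in counts/bin above background (gamma-distributed; sd 0 gives a
#'   degenerate draw).
#' @slot backgroundRate mean off-level counts per bin (>= 0).
#' @slot bleachMean mean of the exponential irreversible photobleach time in
#'   seconds (`Inf` disables bleaching, 0 bleaches at t = 0).
#' @slot startStatePOn probability that a trace starts in the on state.
#' @exportClass MechanismSpec
setClass("MechanismSpec",
  representation(
    classLabel      = "character",
    onFamily        = "character",
    onParams        = "list",
    offFamily       = "character",
    offParams       = "list",
    levelCountProbs = "numeric",
    levelRateMean   = "numeric",
    levelRateSd     = "numeric",
    backgroundRate  = "numeric",
    bleachMean      = "numeric",
    startStatePOn   = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    for (fam in c(object@onFamily, object@offFamily))
      if (!fam %in% .DURATION_FAMILIES)
        msg <- c(msg, sprintf("unknown duration family '%s'", fam))
    ok <- try(validateFamilyParams(object@onFamily, object@onParams),
              silent = TRUE)
    if (inherits(ok, "try-error")) msg <- c(msg, "invalid onParams")
    ok <- try(validateFamilyParams(object@offFamily, object@offParams),
              silent = TRUE)
    if (inherits(ok, "try-error")) msg <- c(msg, "invalid offParams")
    if (any(object@levelCountProbs < 0) ||
        abs(sum(object@levelCountProbs) - 1) > 1e-8)
      msg <- c(msg, "levelCountProbs must be non-negative and sum to 1")
    if (object@levelRateMean <= 0 || object@levelRateSd < 0)
      msg <- c(msg, "level rate mean must be > 0 and sd >= 0")
    if (object@backgroundRate < 0)
      msg <- c(msg, "backgroundRate must be >= 0")
    if (object@bleachMean < 0)
      msg <- c(msg, "bleachMean must be >= 0 (Inf disables bleaching)")
    if (object@startStatePOn < 0 || object@startStatePOn > 1)
      msg <- c(msg, "startStatePOn must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

# ---------------------------------------------------------------------------
# IntervalSequence: alternating on/off renewal realization for one molecule
# ---------------------------------------------------------------------------

#' Alternating on/off interval sequence of one simulated molecule
#'
#' The intermediate product between a [MechanismSpec-class] and a rendered
#' [BlinkingTrace-class]: strictly alternating on/off interval durations, the
#' state of the first interval, the drawn photobleach time, and the
#' piecewise-constant emission-rate schedule (`pieces`) that the renderer
#' integrates over bins. On intervals may contain several constant-rate
#' segments (on-on switching between emissive levels).
#'
#' @slot durations interval durations in seconds (alternating states).
#' @slot startOn logical; state of the first interval.
#' @slot bleachTime photobleach time in seconds (`Inf` if none).
#' @slot pieces data.frame with columns `start`, `end`, `state`
#'   (`"on"`/`"off"`) and `rate` (counts/bin; `NA` for off pieces, rendered at
#'   the background rate).
#' @exportClass IntervalSequence
setClass("IntervalSequence",
  representation(
    durations  = "numeric",
    startOn    = "logical",
    bleachTime = "numeric",
    pieces     = "data.frame"
  ),
  validity = function(object) {
    msg <- character()
    if (any(object@durations <= 0))
      msg <- c(msg, "all interval durations must be > 0")
    if (length(object@bleachTime) != 1L || object@bleachTime < 0)
      msg <- c(msg, "bleachTime must be a single value >= 0")
    p <- object@pieces
    if (nrow(p)) {
      if (!all(c("start", "end", "state", "rate") %in% names(p)))
        msg <- c(msg, "pieces must have start/end/state/rate columns")
      else if (any(p$end <= p$start))
        msg <- c(msg, "pieces must have positive extent")
    }
    if (length(msg)) msg else TRUE
  }
)

# ---------------------------------------------------------------------------
# BlinkingTrace: binned photon counts for one molecule
# ---------------------------------------------------------------------------

#' Binned single-molecule emission-time trace
#'
#' Integer photon counts per fixed time bin (the acquisition unit; 10-ms bins
#' over 150 s in typical confocal blinking experiments), with an optional
#' class label and, for simulated traces, the generative ground truth.
#'
#' @slot counts integer photon counts per bin (>= 0).
#' @slot binTime bin width in seconds (> 0).
#' @slot moleculeId identifier string.
#' @slot classLabel emitter class (`NA_character_` if unknown).
#' @slot groundTruth list; for simulated traces carries the
#'   [IntervalSequence-class] pieces and the per-bin true on-time fraction.
#' @exportClass BlinkingTrace
setClass("BlinkingTrace",
  representation(
    counts      = "integer",
    binTime     = "numeric",
    moleculeId  = "character",
    classLabel  = "character",
    groundTruth = "list"
  ),
  prototype(classLabel = NA_character_, moleculeId = "trace",
            groundTruth = list()),
  validity = function(object) {
    msg <- character()
    if (length(object@counts) < 1L)
      msg <- c(msg, "trace must contain at least one bin")
    if (any(object@counts < 0L, na.rm = TRUE))
      msg <- c(msg, "counts must be non-negative")
    if (length(object@binTime) != 1L || object@binTime <= 0)
      msg <- c(msg, "binTime must be a single positive number")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a BlinkingTrace
#'
#' @param counts non-negative integer photon counts per bin.
#' @param binTime bin width in seconds.
#' @param moleculeId identifier string.
#' @param classLabel optional emitter class label.
#' @param groundTruth optional list of generative ground truth.
#' @return A [BlinkingTrace-class] object.
#' @examples
#' tr <- BlinkingTrace(rpois(100, 5), binTime = 0.01)
#' counts(tr)[1:5]
#' @export
BlinkingTrace <- function(counts, binTime = 0.01, moleculeId = "trace",
                          classLabel = NA_character_, groundTruth = list()) {
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  new("BlinkingTrace", counts = as.integer(round(counts)),
      binTime = binTime, moleculeId = as.character(moleculeId),
      classLabel = as.character(classLabel), groundTruth = groundTruth)
}

# ---------------------------------------------------------------------------
# CriticalValueTable: Monte-Carlo GLR critical values
# ---------------------------------------------------------------------------

#' Monte-Carlo critical values for the change-point likelihood-ratio test
#'
#' The (1 - alpha) quantile of the maximal two-rate Poisson generalized
#' log-likelihood-ratio statistic over constant-rate traces, tabulated on a
#' grid of bin counts. Values for intermediate region sizes are interpolated
#' linearly in log(bin count).
#'
#' @slot nBins grid of region sizes (bins).
#' @slot critValues critical values of the 2*log-GLR statistic per grid point.
#' @slot alpha significance level used.
#' @slot nReplicates Monte-Carlo replicates per grid point.
#' @slot rate reference constant Poisson rate (counts/bin) of the null traces.
#' @slot seed RNG seed used to build the table.
#' @exportClass CriticalValueTable
setClass("CriticalValueTable",
  representation(
    nBins       = "integer",
    critValues  = "numeric",
    alpha       = "numeric",
    nReplicates = "integer",
    rate        = "numeric",
    seed        = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@nBins) != length(object@critValues))
      msg <- c(msg, "nBins and critValues must have equal length")
    if (any(object@critValues <= 0))
      msg <- c(msg, "critical values must be positive")
    if (is.unsorted(object@nBins, strictly = TRUE))
      msg <- c(msg, "nBins grid must be strictly increasing")
    if (object@alpha <= 0 || object@alpha >= 1)
      msg <- c(msg, "alpha must lie in (0, 1)")
    if (length(msg)) msg else TRUE
  }
)

# ---------------------------------------------------------------------------
# Segmentation: change points, segments, intensity levels
# ---------------------------------------------------------------------------

#' Change-point segmentation of a blinking trace
#'
#' Product of the change-point stage: 0-based change-point indices (each
#' marking the first bin of a new segment), per-segment mean intensities,
#' intensity-level assignments after BIC grouping, and on/off labels per
#' level. `nIntensities` records the number of distinct intensities found by
#' grouping (the N_I statistic) before any dim level is merged into off by
#' [labelOnOff()].
#'
#' @slot counts the segmented counts (kept so downstream stages are
#'   self-contained).
#' @slot binTime bin width in seconds.
#' @slot changePoints strictly increasing 0-based bin indices in (0, nBins).
#' @slot segmentLengths bins per segment.
#' @slot segmentMeans mean counts/bin per segment.
#' @slot levelIds per-segment level assignment (1-based; level 1 = lowest
#'   mean).
#' @slot levelMeans mean counts/bin per level, ascending.
#' @slot nIntensities distinct intensities after grouping (N_I);
#'   `NA` until [groupLevels()] has run.
#' @slot onLevels logical per level (length 0 until [labelOnOff()] has run);
#'   level 1 is never on.
#' @slot noiseRms rms noise used for on/off labelling (`NA` until labelled).
#' @exportClass Segmentation
setClass("Segmentation",
  representation(
    counts         = "integer",
    binTime        = "numeric",
    changePoints   = "integer",
    segmentLengths = "integer",
    segmentMeans   = "numeric",
    levelIds       = "integer",
    levelMeans     = "numeric",
    nIntensities   = "integer",
    onLevels       = "logical",
    noiseRms       = "numeric"
  ),
  prototype(nIntensities = NA_integer_, onLevels = logical(0),
            noiseRms = NA_real_),
  validity = function(object) {
    msg <- character()
    n <- length(object@counts)
    cp <- object@changePoints
    if (length(cp) && (is.unsorted(cp, strictly = TRUE) ||
                       any(cp <= 0L) || any(cp >= n)))
      msg <- c(msg, "changePoints must be strictly increasing within (0, nBins)")
    if (length(object@segmentLengths) != length(cp) + 1L)
      msg <- c(msg, "number of segments must equal change points + 1")
    if (sum(object@segmentLengths) != n)
      msg <- c(msg, "segment lengths must sum to the number of bins")
    if (length(object@levelIds) != length(object@segmentLengths))
      msg <- c(msg, "levelIds must have one entry per segment")
    if (length(object@levelIds) &&
        any(object@levelIds > length(object@levelMeans)))
      msg <- c(msg, "levelIds must index levelMeans")
    if (is.unsorted(object@levelMeans))
      msg <- c(msg, "levelMeans must be ascending")
    if (length(object@onLevels) &&
        (length(object@onLevels) != length(object@levelMeans) ||
         isTRUE(object@onLevels[1L])))
      msg <- c(msg, "onLevels must match levels and never mark level 1 as on")
    if (length(msg)) msg else TRUE
  }
)

# ---------------------------------------------------------------------------
# EventTable: segments + intervals taxonomy
# ---------------------------------------------------------------------------

#' Event taxonomy of a labelled segmentation
#'
#' A \emph{segment} is a blinking event at one constant intensity; an
#' \emph{interval} is one or more successive same-state segments bounded by
#' on/off switches (so on-on switching produces multi-segment on intervals).
#' The first and last intervals of a trace are window-censored and flagged.
#'
#' @slot segments data.frame with one row per segment: `segment`, `start_s`,
#'   `end_s`, `duration_s`, `intensity`, `on`, `interval`, `censored`.
#' @slot intervals data.frame with one row per interval: `interval`, `state`,
#'   `duration_s`, `n_segments`, `censored`.
#' @slot binTime bin width in seconds.
#' @exportClass EventTable
setClass("EventTable",
  representation(segments = "data.frame", intervals = "data.frame",
                 binTime = "numeric"),
  validity = function(object) {
    msg <- character()
    s <- object@segments; iv <- object@intervals
    if (nrow(s) && any(s$duration_s <= 0))
      msg <- c(msg, "segment durations must be > 0")
    if (nrow(s) && nrow(iv)) {
      agg <- tapply(s$duration_s, s$interval, sum)
      if (max(abs(agg[as.character(iv$interval)] - iv$duration_s)) > 1e-9)
        msg <- c(msg, "interval durations must equal the sum of their segments")
    }
    if (length(msg)) msg else TRUE
  }
)

# ---------------------------------------------------------------------------
# DistFit: one fitted duration distribution
# ---------------------------------------------------------------------------

#' A fitted event-duration distribution
#'
#' @slot family one of the supported duration families.
#' @slot params named numeric parameters (lognormal: `mu`, `sigma` in log10
#'   seconds; weibull: `shape`, `scale`; exponential: `rate`; power laws:
#'   `alpha`, `xmin` and, when truncated, `cutoffRate`).
#' @slot logLik maximized log-likelihood.
#' @slot ksD Kolmogorov-Smirnov statistic (`NA` until [goodnessOfFit()]).
#' @slot ksP parametric-bootstrap KS p-value (`NA` until computed).
#' @slot n number of durations fitted.
#' @slot fitFloor lower observation floor conditioned on (0 = none).
#' @exportClass DistFit
setClass("DistFit",
  representation(
    family   = "character",
    params   = "numeric",
    logLik   = "numeric",
    ksD      = "numeric",
    ksP      = "numeric",
    n        = "integer",
    fitFloor = "numeric"
  ),
  prototype(ksD = NA_real_, ksP = NA_real_, fitFloor = 0),
  validity = function(object) {
    msg <- character()
    if (!object@family %in% .DURATION_FAMILIES)
      msg <- c(msg, sprintf("unknown family '%s'", object@family))
    if (!is.na(object@ksD) && (object@ksD < 0 || object@ksD > 1))
      msg <- c(msg, "ksD must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

# ---------------------------------------------------------------------------
# MLRModel: multinomial logistic regression with z-score record
# ---------------------------------------------------------------------------

#' Multinomial logistic regression model for BBM
#'
#' Softmax model over K emitter classes: the probability of class j is
#' exp(score_j) / sum_k exp(score_k), where each score is a linear combination
#' of the z-scored blinking statistics plus an intercept, and the last class
#' is the pivot whose coefficients are identically zero.
#'
#' @slot classLabels ordered class labels; the last is the pivot.
#' @slot coefficients (K-1) x (p+1) matrix; one row per non-pivot class,
#'   feature weights followed by the intercept column `(Intercept)`.
#' @slot center,scale per-statistic z-score normalization constants from the
#'   training data (length 0 when the model consumes pre-normalized input).
#' @slot dropped names of zero-variance statistics removed before fitting.
#' @slot lambda ridge penalty applied to the weights (not intercepts).
#' @slot converged logical optimizer status.
#' @exportClass MLRModel
setClass("MLRModel",
  representation(
    classLabels  = "character",
    coefficients = "matrix",
    center       = "numeric",
    scale        = "numeric",
    dropped      = "character",
    lambda       = "numeric",
    converged    = "logical"
  ),
  prototype(center = numeric(0), scale = numeric(0),
            dropped = character(0), lambda = 0, converged = TRUE),
  validity = function(object) {
    msg <- character()
    K <- length(object@classLabels)
    if (K < 2L) msg <- c(msg, "at least two classes are required")
    if (nrow(object@coefficients) != K - 1L)
      msg <- c(msg, "coefficients must have K - 1 rows (pivot fixed at zero)")
    if (length(object@center) &&
        length(object@center) != ncol(object@coefficients) - 1L)
      msg <- c(msg, "normalization record must match the feature count")
    if (length(object@scale) && any(object@scale <= 0))
      msg <- c(msg, "normalization sds must be > 0")
    if (length(msg)) msg else TRUE
  }
)

# ---------------------------------------------------------------------------
# ClassificationReport
# ---------------------------------------------------------------------------

#' Cross-validated classification report
#'
#' @slot confusion true x predicted count matrix (rows = true class).
#' @slot accuracy overall pooled accuracy at the default argmax rule.
#' @slot perClassRecall recall (per-class accuracy) per true class.
#' @slot minClassAccuracy minimum per-class recall.
#' @slot tpr,fpr true/false positive rate (binary problems; `NA` otherwise,
#'   with the first class taken as positive).
#' @slot thresholdCurve data.frame from [thresholdCurve()]: threshold,
#'   accuracy over retained molecules, overall and per-class retention.
#' @slot probabilities pooled out-of-fold class-probability matrix.
#' @slot labels true labels (factor).
#' @slot predicted predicted labels (factor).
#' @slot flags list of diagnostics (e.g. `unstable` when a class has n <= 10).
#' @exportClass ClassificationReport
setClass("ClassificationReport",
  representation(
    confusion        = "matrix",
    accuracy         = "numeric",
    perClassRecall   = "numeric",
    minClassAccuracy = "numeric",
    tpr              = "numeric",
    fpr              = "numeric",
    thresholdCurve   = "data.frame",
    probabilities    = "matrix",
    labels           = "factor",
    predicted        = "factor",
    flags            = "list"
  ),
  validity = function(object) {
    msg <- character()
    if (nrow(object@confusion) != ncol(object@confusion))
      msg <- c(msg, "confusion matrix must be square")
    if (!is.na(object@accuracy) &&
        (object@accuracy < 0 || object@accuracy > 1))
      msg <- c(msg, "accuracy must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)
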