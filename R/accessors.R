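#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("counts", "BlinkingTrace", function(object) object@counts)

#' @rdname accessors
setMethod("counts", "Segmentation", function(object) object@counts)

#' @rdname accessors
setMethod("binTime", "BlinkingTrace", function(object) object@binTime)

#' @rdname accessors
setMethod("binTime", "Segmentation", function(object) object@binTime)

#' @rdname accessors
setMethod("moleculeId", "BlinkingTrace", function(object) object@moleculeId)

#' @rdname accessors
setMethod("classLabel", "BlinkingTrace", function(object) object@classLabel)

#' @rdname accessors
setMethod("changePoints", "Segmentation", function(object) object@changePoints)

#' @rdname accessors
setMethod("segmentMeans", "Segmentation", function(object) object@segmentMeans)

#' @rdname accessors
setMethod("levelMeans", "Segmentation", function(object) object@levelMeans)

#' @rdname accessors
setMethod("nIntensities", "Segmentation", function(object) object@nIntensities)

#' @rdname accessors
setMethod("onLevels", "Segmentation", function(object) object@onLevels)

#' @rdname accessors
setMethod("fitFamily", "DistFit", function(object) object@family)

#' @rdname accessors
setMethod("fitParams", "DistFit", function(object) object@params)

#' @rdname accessors
setMethod("ksStat", "DistFit", function(object) object@ksD)

#' @rdname accessors
setMethod("segments", "EventTable", function(object) object@segments)

#' @rdname accessors
setMethod("intervals", "EventTable", function(object) object@intervals)

setMethod("show", "BlinkingTrace", function(object) {
  cat(sprintf("BlinkingTrace '%s' (%s): %d bins x %.3g s = %.4g s, mean %.3g counts/bin\n",
              object@moleculeId,
              ifelse(is.na(object@classLabel), "unlabelled", object@classLabel),
              length(object@counts), object@binTime,
              length(object@counts) * object@binTime,
              mean(object@counts)))
})

setMethod("show", "MechanismSpec", function(object) {
  cat(sprintf("MechanismSpec '%s'\n", object@classLabel))
  cat(sprintf("  on : %s (%s)\n", object@onFamily,
              paste(names(object@onParams), unlist(object@onParams),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  off: %s (%s)\n", object@offFamily,
              paste(names(object@offParams), unlist(object@offParams),
                    sep = "=", collapse = ", ")))
  cat(sprintf("  levels: up to %d, rate %.3g +/- %.3g counts/bin over background %.3g; bleach mean %.3g s\n",
              length(object@levelCountProbs), object@levelRateMean,
              object@levelRateSd, object@backgroundRate, object@bleachMean))
})

setMethod("show", "Segmentation", function(object) {
  cat(sprintf("Segmentation: %d bins, %d change points, %d segments\n",
              length(object@counts), length(object@changePoints),
              length(object@segmentLengths)))
  if (!is.na(object@nIntensities))
    cat(sprintf("  %d distinct intensities (levels: %s)\n",
                object@nIntensities,
                paste(sprintf("%.3g", object@levelMeans), collapse = ", ")))
  if (length(object@onLevels))
    cat(sprintf("  on levels: %s (noise rms %.3g)\n",
                paste(which(object@onLevels), collapse = ", "),
                object@noiseRms))
})

setMethod("show", "CriticalValueTable", function(object) {
  cat(sprintf("CriticalValueTable: alpha = %g, %d replicates at rate %.3g counts/bin (seed %d)\n",
              object@alpha, object@nReplicates, object@rate, object@seed))
  print(setNames(round(object@critValues, 3), object@nBins))
})

setMethod("show", "EventTable", function(object) {
  cat(sprintf("EventTable: %d segments in %d intervals (%d on, %d off)\n",
              nrow(object@segments), nrow(object@intervals),
              sum(object@intervals$state == "on"),
              sum(object@intervals$state == "off")))
})

setMethod("show", "DistFit", function(object) {
  cat(sprintf("DistFit [%s], n = %d%s\n", object@family, object@n,
              if (object@fitFloor > 0)
                sprintf(" (conditioned on t >= %g s)", object@fitFloor) else ""))
  cat("  ", paste(names(object@params), signif(object@params, 4),
                  sep = " = ", collapse = ", "), "\n", sep = "")
  cat(sprintf("  logLik = %.2f, KS D = %s, KS p = %s\n", object@logLik,
              ifelse(is.na(object@ksD), "NA", sprintf("%.4f", object@ksD)),
              ifelse(is.na(object@ksP), "NA", sprintf("%.3f", object@ksP))))
})

setMethod("show", "MLRModel", function(object) {
  cat(sprintf("MLRModel: %d classes (pivot '%s'), %d features, ridge %g\n",
              length(object@classLabels),
              object@classLabels[length(object@classLabels)],
              ncol(object@coefficients) - 1L, object@lambda))
  print(round(object@coefficients, 3))
})

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf("ClassificationReport: accuracy %.1f%%, min per-class %.1f%%\n",
              100 * object@accuracy, 100 * object@minClassAccuracy))
  cat("Confusion (rows = true):\n")
  print(object@confusion)
  if (!is.na(object@tpr))
    cat(sprintf("TPR %.2f, FPR %.2f\n", object@tpr, object@fpr))
})

#' Extract report components
#'
#' @param report a [ClassificationReport-class].
#' @return `confusionMatrix` returns the true-by-predicted count matrix;
#'   `reportAccuracy` the overall pooled accuracy; `minClassAccuracy` the
#'   minimum per-class recall; `reportThresholdCurve` the threshold vs
#'   accuracy/retention data.frame.
#' @export
confusionMatrix <- function(report) report@confusion

#' @rdname confusionMatrix
#' @export
reportAccuracy <- function(report) report@accuracy

#' @rdname confusionMatrix
#' @export
minClassAccuracy <- function(report) report@minClassAccuracy

#' @rdname confusionMatrix
#' @export
reportThresholdCurve <- function(report) report@thresholdCurve
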