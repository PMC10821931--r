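#' @include AllClasses.R
NULL

#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated list:
#' acquisition geometry (bin time, window), optional common truncation,
#' change-point settings (significance level, critical-value grid and
#' replicates), censoring policy, candidate duration families,
#' cross-validation folds and the probability-threshold grid.
#'
#' @param specs list of [MechanismSpec-class] objects, or a YAML path for
#'   [readMechanismSpecs()]; `NULL` if an existing population is supplied to
#'   [runPipeline()].
#' @param seed master integer seed (mandatory; all stage randomness derives
#'   from it).
#' @param nPerClass simulated molecules per class.
#' @param binTime bin width in seconds.
#' @param window trace duration in seconds.
#' @param truncationS optional common analysis window (e.g. 100 s when a
#'   class was acquired over a shorter window).
#' @param alpha change-point significance level.
#' @param cvNBinsGrid,cvReplicates critical-value table grid and Monte-Carlo
#'   replicates.
#' @param includeCensored include window-censored events in per-trace
#'   averages (they are always excluded from duration fits).
#' @param families candidate duration families for [selectFamily()].
#' @param folds cross-validation folds.
#' @param thresholds probability-threshold grid within [1/K, 1).
#' @param outputDir directory for report files (`NULL` skips writing).
#' @return A validated configuration list of class `blinkPipelineConfig`.
#' @export
pipelineConfig <- function(specs = NULL, seed = 1, nPerClass = 25,
                           binTime = 0.01, window = 150,
                           truncationS = NULL, alpha = 0.05,
                           cvNBinsGrid = NULL, cvReplicates = 500,
                           includeCensored = TRUE,
                           families = c("lognormal", "weibull",
                                        "exponential", "power_law"),
                           folds = 10,
                           thresholds = seq(0.5, 0.95, by = 0.05),
                           outputDir = NULL) {
  stopifnot_scalar(binTime, "binTime", positive = TRUE)
  stopifnot_scalar(window, "window", positive = TRUE)
  if (!is.null(truncationS))
    stopifnot_scalar(truncationS, "truncationS", positive = TRUE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  if (folds < 2) stop("'folds' must be >= 2")
  if (any(thresholds < 0) || any(thresholds >= 1))
    stop("'thresholds' must lie in [0, 1)")
  if (is.character(specs)) specs <- readMechanismSpecs(specs)
  cfg <- list(specs = specs, seed = as.integer(seed),
              nPerClass = nPerClass, binTime = binTime, window = window,
              truncationS = truncationS, alpha = alpha,
              cvNBinsGrid = cvNBinsGrid, cvReplicates = cvReplicates,
              includeCensored = includeCensored, families = families,
              folds = folds, thresholds = thresholds,
              outputDir = outputDir)
  class(cfg) <- "blinkPipelineConfig"
  cfg
}

configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config[setdiff(names(config), "outputDir")], file = f,
       control = c("all", "digits17"))
  unname(tools::md5sum(f))
}

#' Run the full blink-based multiplexing pipeline
#'
#' Chains every stage: simulate (or accept) a labelled trace population,
#' optionally truncate, detect change points and label levels, extract the
#' ten blinking statistics, fit duration distributions to the pooled
#' uncensored on/off intervals of each class, cross-validate the multinomial
#' logistic classifier, and compute the threshold/accuracy/retention curve.
#' Deterministic given the configuration seed. When `outputDir` is set the
#' statistics table, duration-fit report, model, confusion matrix and
#' threshold curve are written there together with a provenance record
#' (configuration hash, master seed, package version).
#'
#' @param config a `blinkPipelineConfig` from [pipelineConfig()].
#' @param population optional list of [BlinkingTrace-class] objects; when
#'   supplied the simulation stage is skipped.
#' @param verbose emit per-stage progress messages with molecule counts.
#' @return List with `population`, `stats` (data.frame), `fits` (per class:
#'   ranked on/off interval fits), `model` (full-data [MLRModel-class] for
#'   coefficient interpretation), `report` (fold-internal
#'   [ClassificationReport-class]), `curve`, and `provenance`.
#' @export
runPipeline <- function(config, population = NULL, verbose = TRUE) {
  if (!inherits(config, "blinkPipelineConfig"))
    stop("'config' must come from pipelineConfig()")
  say <- function(...) if (verbose) message(sprintf(...))

  if (is.null(population)) {
    if (is.null(config$specs))
      stop("config has no mechanism specs and no population was supplied")
    say("simulate: %d classes x %d molecules, %g s at %g s bins",
        length(config$specs), config$nPerClass, config$window,
        config$binTime)
    population <- simulatePopulation(config$specs, config$nPerClass,
                                     window = config$window,
                                     binTime = config$binTime,
                                     seed = config$seed)
  }
  if (!is.null(config$truncationS)) {
    population <- lapply(population, truncateTrace,
                         windowS = config$truncationS)
    say("truncate: all traces to %g s (%d bins)", config$truncationS,
        length(counts(population[[1L]])))
  }

  n <- max(vapply(population, function(tr) length(counts(tr)), numeric(1)))
  grid <- config$cvNBinsGrid %||%
    unique(round(exp(seq(log(8), log(max(n, 9)), length.out = 6))))
  rate <- max(mean(vapply(population, function(tr) mean(counts(tr)),
                          numeric(1))), 0.5)
  say("detect: critical values on grid {%s} (alpha %g, %d replicates)",
      paste(grid, collapse = ", "), config$alpha, config$cvReplicates)
  table <- estimateCriticalValues(grid, alpha = config$alpha,
                                  nReplicates = config$cvReplicates,
                                  rate = rate,
                                  seed = deriveSeed(config$seed, 0L, 3L))

  segs <- lapply(population, segmentTrace, table = table)
  events <- lapply(segs, buildEventTable)
  say("stats: %d molecules segmented", length(segs))
  stats <- do.call(rbind, lapply(seq_along(population), function(i) {
    cbind(data.frame(molecule_id = moleculeId(population[[i]]),
                     class_label = classLabel(population[[i]]),
                     stringsAsFactors = FALSE),
          computeStatVector(events[[i]], segs[[i]],
                            includeCensored = config$includeCensored))
  }))
  rownames(stats) <- NULL

  classes <- unique(stats$class_label)
  fits <- lapply(setNames(classes, classes), function(cl) {
    evs <- events[stats$class_label == cl]
    out <- list()
    for (state in c("on", "off")) {
      d <- poolDurations(evs, state = state, kind = "interval")
      out[[state]] <- if (length(d) >= 10)
        selectFamily(d, config$families, fitFloor = config$binTime,
                     seed = deriveSeed(config$seed, 0L, 4L))
      else NULL
    }
    out
  })
  say("fitdist: pooled interval durations fitted for %d classes",
      length(classes))

  feats <- stats[, statNames()]
  labels <- factor(stats$class_label)
  z <- zscoreFitApply(feats)
  model <- fitMLR(z$train, labels, center = z$center, scale = z$scale,
                  dropped = z$dropped)
  report <- crossValidate(feats, labels, folds = config$folds,
                          seed = deriveSeed(config$seed, 0L, 5L),
                          thresholds = config$thresholds)
  say("evaluate: pooled CV accuracy %.1f%% (min class %.1f%%), %d molecules",
      100 * report@accuracy, 100 * report@minClassAccuracy, nrow(stats))

  provenance <- list(config_hash = configHash(config),
                     seed = config$seed,
                     package_version =
                       as.character(utils::packageVersion("blinkMux")),
                     n_molecules = nrow(stats))

  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    writeStatTable(stats, file.path(config$outputDir, "stats.tsv"))
    writeFitReport(fits, file.path(config$outputDir, "duration_fits.json"))
    writeModel(model, file.path(config$outputDir, "mlr_model.json"))
    write.table(report@confusion,
                file.path(config$outputDir, "confusion.tsv"),
                sep = "\t", quote = FALSE)
    write.table(report@thresholdCurve,
                file.path(config$outputDir, "threshold_curve.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(provenance,
                         file.path(config$outputDir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(population = population, stats = stats, fits = fits, model = model,
       report = report, curve = report@thresholdCurve,
       provenance = provenance)
}
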