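# File formats, configuration, end-to-end pipeline.

test_that("traces round-trip through the text format exactly", {
  tr <- BlinkingTrace(rpois(500, 3), binTime = 0.01, moleculeId = "m7",
                      classLabel = "R6G")
  p <- withr::local_tempfile(fileext = ".txt")
  writeTrace(tr, p, extra = c(seed = "11"))
  back <- readTrace(p)
  expect_identical(counts(back), counts(tr))
  expect_identical(binTime(back), binTime(tr))
  expect_identical(moleculeId(back), "m7")
  expect_identical(classLabel(back), "R6G")
})

test_that("population loading validates files, counts and bin times", {
  d <- withr::local_tempdir()
  pop <- simulatePopulation(list(presetSpec("R6G"), presetSpec("AZ")),
                            nPerClass = 3, window = 2, seed = 5)
  man <- writePopulation(pop, d)
  back <- loadPopulation(man)
  expect_length(back, 6)
  expect_identical(lapply(back, counts), lapply(pop, counts))
  expect_identical(vapply(back, classLabel, character(1)),
                   vapply(pop, classLabel, character(1)))

  # corrupt one count: error names file and line
  f <- file.path(d, "R6G_002.txt")
  lines <- readLines(f)
  lines[10] <- "-3"
  writeLines(lines, f)
  expect_error(loadPopulation(man), "R6G_002.*line 10")

  # empty manifest
  m2 <- file.path(d, "empty.tsv")
  writeLines("molecule_id\tclass_label\tfile", m2)
  expect_error(loadPopulation(m2), "empty population")

  # inconsistent bin times
  writeLines(lines <- c("# bin_time_s: 0.02", "# molecule_id: odd",
                        "# class_label: AZ", "1", "2"),
             file.path(d, "odd.txt"))
  writeTrace(pop[[1]], file.path(d, "R6G_002.txt"))  # restore
  man3 <- file.path(d, "mixed.tsv")
  writeLines(c("molecule_id\tclass_label\tfile",
               "R6G_001\tR6G\tR6G_001.txt",
               "odd\tAZ\todd.txt"), man3)
  expect_error(loadPopulation(man3), "inconsistent bin_time")
})

test_that("mechanism specs load from YAML with presets and overrides", {
  p <- withr::local_tempfile(fileext = ".yml")
  writeLines(c(
    "R6G:",
    "  preset: R6G",
    "myDye:",
    "  onFamily: lognormal",
    "  onParams: {mu: 0.5, sigma: 1.2}",
    "  offFamily: weibull",
    "  offParams: {shape: 0.6, scale: 0.4}",
    "  bleachMean: 40"), p)
  specs <- readMechanismSpecs(p)
  expect_length(specs, 2)
  expect_equal(specs$R6G@offParams$mu, -1.27)
  expect_equal(specs$myDye@offFamily, "weibull")
  expect_equal(specs$myDye@bleachMean, 40)
})

test_that("statistic tables and models round-trip at full precision", {
  sv <- simulateStatVectors(list(A = refStatMeans, B = refStatMeans + 1),
                            list(A = refStatSds, B = refStatSds),
                            30, seed = 6)
  p <- withr::local_tempfile(fileext = ".tsv")
  writeStatTable(sv, p)
  back <- readStatTable(p)
  expect_equal(back[, statNames()], sv[, statNames()], tolerance = 1e-14)

  z <- zscoreFitApply(sv[, statNames()])
  m <- fitMLR(z$train, sv$class_label, center = z$center, scale = z$scale)
  pm <- withr::local_tempfile(fileext = ".json")
  writeModel(m, pm)
  m2 <- readModel(pm)
  expect_equal(m2@coefficients, m@coefficients, tolerance = 1e-14)
  probsA <- predictProba(m, sv[, statNames()])
  probsB <- predictProba(m2, sv[, statNames()])
  expect_equal(probsA, probsB, tolerance = 1e-12)
})

test_that("the pipeline is deterministic and honors truncation", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- function(out) pipelineConfig(
    specs = list(presetSpec("R6G"), presetSpec("AZ")),
    seed = 17, nPerClass = 12, window = 20, truncationS = 15,
    cvReplicates = 300, folds = 3,
    families = c("lognormal", "exponential"),
    outputDir = out)
  r1 <- runPipeline(cfg(d1), verbose = FALSE)
  r2 <- runPipeline(cfg(d2), verbose = FALSE)

  # truncation: 15 s at 10-ms bins
  expect_true(all(vapply(r1$population, function(tr)
    length(counts(tr)), numeric(1)) == 1500))
  # byte-identical reports under the same seed
  expect_identical(readLines(file.path(d1, "stats.tsv")),
                   readLines(file.path(d2, "stats.tsv")))
  expect_identical(readLines(file.path(d1, "threshold_curve.tsv")),
                   readLines(file.path(d2, "threshold_curve.tsv")))
  expect_equal(r1$provenance$config_hash, r2$provenance$config_hash)
  expect_equal(nrow(r1$stats), 24)
  expect_s4_class(r1$model, "MLRModel")
  expect_s4_class(r1$report, "ClassificationReport")
  expect_true(file.exists(file.path(d1, "duration_fits.json")))
  expect_true(file.exists(file.path(d1, "provenance.json")))
})

test_that("three-class runs report per-class retention at every threshold", {
  sv <- simulateStatVectors(
    list(A = refStatMeans, B = refStatMeans + 2, C = refStatMeans - 2),
    list(A = refStatSds, B = refStatSds, C = refStatSds),
    40, seed = 8)
  r <- crossValidate(sv[, statNames()], sv$class_label, folds = 4,
                     seed = 9, thresholds = seq(0.4, 0.9, 0.1))
  curve <- reportThresholdCurve(r)
  expect_true(all(c("retention_A", "retention_B", "retention_C")
                  %in% names(curve)))
  expect_equal(nrow(curve), 6)
  expect_true(all(curve$retention >= 0 & curve$retention <= 1))
})

test_that("pipeline configuration is validated", {
  expect_error(pipelineConfig(seed = 1, binTime = 0), "binTime")
  expect_error(pipelineConfig(seed = 1, alpha = 0), "alpha")
  expect_error(pipelineConfig(seed = 1, folds = 1), "folds")
  expect_error(pipelineConfig(seed = 1, thresholds = c(0.5, 1)),
               "thresholds")
  expect_error(runPipeline(list()), "pipelineConfig")
})
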