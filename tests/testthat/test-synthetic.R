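# Synthetic blinking-trace generator.

test_that("duration sampling matches the closed-form laws", {
  # degenerate lognormal collapses onto its median 10^mu
  d <- sampleDurations("lognormal", list(mu = 0, sigma = 1e-12), 5, seed = 1)
  expect_equal(d, rep(1, 5), tolerance = 1e-9)

  # lognormal: sample median ~ 10^mu, log10 moments converge to (mu, sigma)
  d <- sampleDurations("lognormal", list(mu = 0.01, sigma = 1.9), 1e5,
                       seed = 2)
  expect_true(all(d > 0))
  expect_lt(abs(median(log10(d)) - 0.01), 3 * 1.9 * sqrt(pi / 2) / sqrt(1e5))
  expect_lt(abs(mean(log10(d)) - 0.01), 3 * 1.9 / sqrt(1e5))
  expect_lt(abs(sd(log10(d)) - 1.9), 3 * 1.9 / sqrt(2 * 1e5))

  # exponential mean = 1/rate
  d <- sampleDurations("exponential", list(rate = 2), 1e5, seed = 3)
  expect_lt(abs(mean(d) - 0.5), 3 * 0.5 / sqrt(1e5))

  # pure power law: median = xmin * 2^(1/(alpha-1))
  d <- sampleDurations("power_law", list(alpha = 2, xmin = 0.01), 4e4,
                       seed = 4)
  expect_true(all(d >= 0.01))
  expect_lt(abs(median(d) - 0.02), 0.002)

  # exponential cutoff suppresses the tail relative to the pure power law
  dt <- sampleDurations("truncated_power_law",
                        list(alpha = 2, xmin = 0.01, cutoffRate = 5),
                        4e4, seed = 4)
  expect_true(all(dt >= 0.01))
  expect_lt(quantile(dt, 0.99), quantile(d, 0.99))
})

test_that("duration sampling is reproducible and validates parameters", {
  a <- sampleDurations("weibull", list(shape = 0.5, scale = 0.5), 100,
                       seed = 9)
  b <- sampleDurations("weibull", list(shape = 0.5, scale = 0.5), 100,
                       seed = 9)
  expect_identical(a, b)
  expect_error(sampleDurations("gamma", list(), 5), "unknown")
  expect_error(sampleDurations("lognormal", list(mu = 0, sigma = 0), 5),
               "sigma")
  expect_error(sampleDurations("power_law", list(alpha = 1, xmin = 1), 5),
               "alpha")
  expect_error(sampleDurations("lognormal", list(mu = 0, sigma = 1), 0),
               "n")
})

test_that("simulated molecules respect bleaching and degenerate limits", {
  spec0 <- mechanismSpec("dead", bleachMean = 0)
  sq <- simulateMolecule(spec0, 150, seed = 1)
  expect_true(all(sq@pieces$state == "off"))

  specOn <- mechanismSpec("alwayson",
                          onParams = list(mu = 6, sigma = 1e-9),
                          levelCountProbs = 1, levelRateSd = 0,
                          bleachMean = Inf, startStatePOn = 1)
  sq <- simulateMolecule(specOn, 150, seed = 2)
  onPieces <- sq@pieces[sq@pieces$state == "on", ]
  expect_equal(min(onPieces$start), 0)
  expect_gte(max(onPieces$end), 150)
})

test_that("interval sequences follow the alternating renewal law", {
  # dispersive-ET kinetics without bleaching, so the pure renewal process is
  # the exact law; bleaching is tested separately above
  spec <- mechanismSpec("renewal", onParams = list(mu = 0.01, sigma = 1.9),
                        offParams = list(mu = -1.27, sigma = 2.07),
                        bleachMean = Inf)
  nTr <- 300
  got <- vapply(seq_len(nTr), function(i) {
    sq <- simulateMolecule(spec, 150, seed = i)
    states <- sq@pieces$state
    # strict alternation at the interval level
    nOnInt <- sum(rle(states)$values == "on")
    nOnInt
  }, numeric(1))
  set.seed(777)
  want <- replicate(nTr, {
    startOn <- runif(1) < 0.5
    oracleRenewalOnCount(0.01, 1.9, -1.27, 2.07, 150, startOn)
  })
  # means agree within 3 standard errors of the difference
  seDiff <- sqrt(var(got) / nTr + var(want) / nTr)
  expect_lt(abs(mean(got) - mean(want)), 3 * seDiff)
})

test_that("rendering follows the Poisson forward model", {
  # single on interval at rate 5, no background: Poisson(5) bins
  sq <- intervalSequence(200, startOn = TRUE, onRates = 5)
  tr <- renderTrace(sq, backgroundRate = 0, binTime = 0.01, window = 150,
                    seed = 1)
  x <- counts(tr)
  expect_length(x, 15000)
  expect_lt(abs(mean(x) - 5), 3 * sqrt(5 / 15000))
  expect_lt(abs(var(x) - 5), 0.3)

  # all-off at background 0.2: total ~ Poisson(0.2 * nBins)
  sq <- intervalSequence(200, startOn = FALSE, onRates = 5)
  tr <- renderTrace(sq, backgroundRate = 0.2, binTime = 0.01, window = 150,
                    seed = 2)
  tot <- sum(counts(tr))
  expect_lt(abs(tot - 0.2 * 15000), 4 * sqrt(0.2 * 15000))

  # a bin straddling an on->off switch halfway gets half the on rate
  sq <- intervalSequence(c(0.005, 0.005), startOn = TRUE, onRates = 1000)
  one <- vapply(1:200, function(s)
    counts(renderTrace(sq, backgroundRate = 0, binTime = 0.01,
                       window = 0.01, seed = s))[1], numeric(1))
  expect_lt(abs(mean(one) - 500), 4 * sqrt(500 / 200))

  expect_error(renderTrace(sq, backgroundRate = -1), ">= 0")
})

test_that("ground-truth on fraction matches the interval sequence", {
  spec <- presetSpec("R6G")
  for (s in 1:5) {
    sq <- simulateMolecule(spec, 30, seed = s)
    tr <- renderTrace(sq, backgroundRate = 0.2, binTime = 0.01,
                      window = 30, seed = s + 100)
    onFrac <- tr@groundTruth$onFraction
    p <- sq@pieces
    p$end <- pmin(p$end, 30)
    p <- p[p$end > p$start, ]
    trueOn <- sum((p$end - p$start)[p$state == "on"])
    nSwitch <- nrow(p)
    expect_lt(abs(sum(onFrac) * 0.01 - trueOn), (nSwitch + 1) * 0.01)
  }
})

test_that("population simulation is labelled and bit-reproducible", {
  specs <- list(presetSpec("R6G"), presetSpec("AZ"))
  popA <- simulatePopulation(specs, 3, window = 5, seed = 11)
  popB <- simulatePopulation(specs, 3, window = 5, seed = 11)
  expect_length(popA, 6)
  expect_equal(unname(table(vapply(popA, classLabel, character(1)))),
               c(3L, 3L), ignore_attr = TRUE)
  expect_identical(lapply(popA, counts), lapply(popB, counts))
  popC <- simulatePopulation(specs, 3, window = 5, seed = 12)
  expect_false(identical(lapply(popA, counts), lapply(popC, counts)))
  expect_error(simulatePopulation(list(), 3), "at least one")
})

test_that("feature-space generator reproduces the class geometry", {
  # sd = 0 collapses every vector onto the class mean
  x <- simulateStatVectors(list(A = refStatMeans), list(A = rep(0, 10)),
                           5, seed = 1)
  expect_equal(unname(as.matrix(x[, statNames()])),
               matrix(refStatMeans, 5, 10, byrow = TRUE))

  # a 3-sd shift in one coordinate shows up as a 3-sd sample distance
  m2 <- refStatMeans
  m2[2] <- m2[2] + 3 * refStatSds[2]
  x <- simulateStatVectors(list(A = refStatMeans, B = m2),
                           list(A = refStatSds, B = refStatSds),
                           400, seed = 2)
  dsep <- (mean(x$I_min[x$class_label == "B"]) -
             mean(x$I_min[x$class_label == "A"])) / refStatSds[2]
  expect_lt(abs(dsep - 3), 3 * sqrt(2 / 400))

  expect_error(simulateStatVectors(list(A = 1:5), list(A = rep(1, 5)), 5),
               "10 means")
})
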