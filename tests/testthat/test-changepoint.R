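# Change-point detection, level grouping, on/off labelling.

test_that("critical values are monotone in alpha and reproducible", {
  lax <- estimateCriticalValues(100, alpha = 0.5, nReplicates = 400,
                                seed = 5)
  strict <- estimateCriticalValues(100, alpha = 0.05, nReplicates = 400,
                                   seed = 5)
  expect_lt(lax@critValues, strict@critValues)
  again <- estimateCriticalValues(100, alpha = 0.05, nReplicates = 400,
                                  seed = 5)
  expect_identical(strict@critValues, again@critValues)
  expect_error(estimateCriticalValues(100, alpha = 1.2), "alpha")
})

test_that("a clear step is found at the true bin and matches the scan oracle", {
  # strict alpha so recursion rarely splits the flanks of the true step
  tab <- estimateCriticalValues(c(64, 256, 1000), alpha = 0.01,
                                nReplicates = 1000, rate = 5, seed = 7)
  set.seed(21)
  nCps <- integer(40)
  for (r in 1:40) {
    x <- c(rpois(500, 1), rpois(500, 20))
    seg <- detectChangePoints(BlinkingTrace(x), tab)
    got <- changePoints(seg)
    nCps[r] <- length(got)
    # the true switch is always recovered within +-2 bins ...
    expect_true(any(abs(got - 500) <= 2))
    # ... at exactly the split an exhaustive likelihood scan would pick
    expect_true(oracleBestSplit(x)$k %in% got)
  }
  # spurious extra splits stay at the few-percent-per-region level
  expect_gte(mean(nCps == 1L), 0.85)
})

test_that("selected splits equal the exhaustive likelihood scan on small traces", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(16:64, 1)
    nCp <- sample(0:2, 1)
    cp <- sort(sample(seq(4, n - 4), nCp))
    rates <- 1 + 15 * (seq_len(nCp + 1) %% 2)
    x <- unlist(lapply(seq_len(nCp + 1), function(i) {
      lo <- if (i == 1) 1 else cp[i - 1] + 1
      hi <- if (i > nCp) n else cp[i]
      rpois(hi - lo + 1, rates[i])
    }))
    g <- blinkMux:::glrSplitStats(x, 2L)
    orc <- oracleBestSplit(x)
    expect_identical(g$k[which.max(g$stat)], orc$k)
    # identical statistic up to Poisson-factorial cancellation
    expect_equal(max(g$stat), 2 * (orc$splitLL - orc$nullLL),
                 tolerance = 1e-8)
  }
})

test_that("false-positive rate on constant traces is near alpha", {
  tab <- estimateCriticalValues(200, alpha = 0.05, nReplicates = 1500,
                                rate = 5, seed = 8)
  set.seed(9)
  fp <- mean(vapply(1:200, function(i) {
    seg <- detectChangePoints(BlinkingTrace(rpois(200, 5)), tab)
    length(changePoints(seg)) > 0
  }, logical(1)))
  # binomial 99% band around 0.05 at 200 draws
  expect_gte(fp, 0.0)
  expect_lte(fp, 0.05 + 2.6 * sqrt(0.05 * 0.95 / 200))
})

test_that("degenerate traces yield a single segment", {
  tab <- sharedCritTable()
  seg <- detectChangePoints(BlinkingTrace(rep(0L, 300)), tab)
  expect_length(changePoints(seg), 0)
  expect_equal(segmentMeans(seg), 0)
})

test_that("level grouping follows the BIC merge criterion", {
  tab <- sharedCritTable()
  # two segments with the same generative rate collapse to one level
  set.seed(41)
  seg <- makeSegmentation(c(500, 500), c(5.02, 4.97), c(2, 1),
                          c(4.97, 5.02))
  g <- groupLevels(seg)
  expect_equal(nIntensities(g), 1)

  # rates 1,10,10,1 over 500-bin segments give exactly two levels,
  # in agreement with a hand-coded BIC comparison
  set.seed(42)
  means <- c(mean(rpois(500, 1)), mean(rpois(500, 10)),
             mean(rpois(500, 10)), mean(rpois(500, 1)))
  seg <- makeSegmentation(rep(500, 4), means, rank(means,
                                                   ties.method = "first"),
                          sort(means))
  g <- groupLevels(seg)
  expect_equal(nIntensities(g), 2)
  # oracle: merging the two 10s is favored, merging 1s with 10s is not
  llv <- function(S, L) ifelse(S > 0, S * log(S / L), 0)
  S <- means * 500
  dKeepApart <- 2 * (llv(S[2], 500) + llv(S[3], 500) -
                       llv(S[2] + S[3], 1000))
  expect_lte(dKeepApart, log(2000))
  dCross <- 2 * (llv(S[1] + S[4], 1000) + llv(S[2] + S[3], 1000) -
                   llv(sum(S), 2000))
  expect_gt(dCross, log(2000))

  # single segment stays one level
  seg <- makeSegmentation(100, 3, 1, 3)
  expect_equal(nIntensities(groupLevels(seg)), 1)
})

test_that("on/off labelling applies the one-sigma-above-noise rule", {
  seg <- makeSegmentation(c(100, 100), c(0.5, 8), c(1, 2), c(0.5, 8))
  lab <- labelOnOff(seg, noiseRms = 1)
  expect_equal(onLevels(lab), c(FALSE, TRUE))

  # 1.2 <= 0.5 + 1.0: the dim level is merged into off
  seg <- makeSegmentation(c(100, 100), c(0.5, 1.2), c(1, 2), c(0.5, 1.2))
  lab <- labelOnOff(seg, noiseRms = 1)
  expect_equal(onLevels(lab), FALSE)
  expect_length(levelMeans(lab), 1)
  expect_equal(levelMeans(lab), 0.85)   # pooled off mean
  expect_equal(nIntensities(lab), 2)    # N_I preserved from grouping

  # single level is off by definition
  seg <- makeSegmentation(100, 3, 1, 3)
  lab <- labelOnOff(seg, noiseRms = 1)
  expect_equal(onLevels(lab), FALSE)

  expect_error(labelOnOff(makeSegmentation(100, 3, 1, 3,
                                           nIntensities = NA)),
               "grouped")
})

test_that("well-separated synthetic switches are recovered within two bins", {
  tab <- sharedCritTable()
  set.seed(55)
  hits <- 0L
  tries <- 0L
  for (i in 1:20) {
    cps <- c(250, 500, 750)
    x <- c(rpois(250, 0.2), rpois(250, 10), rpois(250, 0.2),
           rpois(250, 10))
    seg <- segmentTrace(BlinkingTrace(x), tab)
    got <- changePoints(seg)
    for (cp in cps) {
      tries <- tries + 1L
      if (any(abs(got - cp) <= 2)) hits <- hits + 1L
    }
  }
  expect_gte(hits / tries, 0.95)
})

test_that("segmentation tables serialize the half-open bin ranges", {
  tab <- sharedCritTable()
  set.seed(66)
  x <- c(rpois(300, 0.2), rpois(300, 12))
  seg <- segmentTrace(BlinkingTrace(x), tab)
  df <- segmentationTable(seg)
  expect_equal(df$start_bin[1], 0)
  expect_equal(df$end_bin[nrow(df)], 600)
  expect_true(all(df$end_bin > df$start_bin))
  expect_equal(sum(df$end_bin - df$start_bin), 600)
})
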