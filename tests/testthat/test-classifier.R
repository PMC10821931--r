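# Multinomial logistic classification, thresholding, retention.

binaryCloud <- function(sep, n = 150, seed = 1) {
  m2 <- refStatMeans
  m2[2] <- m2[2] + sep * refStatSds[2]
  simulateStatVectors(list(A = refStatMeans, B = m2),
                      list(A = refStatSds, B = refStatSds),
                      nPerClass = n, seed = seed)
}

test_that("z-score normalization is fitted on training data only", {
  x <- matrix(rnorm(200), 50, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  z <- zscoreFitApply(x, x)
  expect_equal(unname(colMeans(z$train)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(z$train, 2, sd)), rep(1, 4), tolerance = 1e-12)
  expect_identical(z$train, z$test)

  xc <- cbind(x, e = 7)
  z <- zscoreFitApply(xc)
  expect_equal(z$dropped, "e")
  expect_false("e" %in% colnames(z$train))

  shifted <- sweep(x, 2, apply(x, 2, sd), `+`)
  z <- zscoreFitApply(x, shifted)
  expect_equal(unname(colMeans(z$test) - colMeans(z$train)), rep(1, 4),
               tolerance = 1e-12)
})

test_that("softmax probabilities behave as Eq.-style linear scores", {
  # all-zero coefficients: uniform probabilities
  m0 <- new("MLRModel", classLabels = c("A", "B"),
            coefficients = matrix(0, 1, 11,
                                  dimnames = list("A",
                                                  c(statNames(),
                                                    "(Intercept)"))))
  p <- predictProba(m0, matrix(0, 1, 10))
  expect_equal(unname(p[1, ]), c(0.5, 0.5))

  # a fitted binary discriminant evaluated at the z-score origin:
  # score = intercept, P = logistic(intercept)
  coefs <- c(N_I = -0.4, I_min = -2.7, I_max = 0.4, I_t_avg = -0.7,
             t_on_seg = -0.3, t_off_seg = -0.2, t_on_int = 0.4,
             t_off_int = 0.2, N_on_seg = 0.6, N_off_seg = -0.8,
             `(Intercept)` = -1.3)
  m <- new("MLRModel", classLabels = c("A", "B"),
           coefficients = matrix(coefs, 1,
                                 dimnames = list("A", names(coefs))))
  p <- predictProba(m, matrix(0, 1, 10))
  score <- log(p[1, "A"] / p[1, "B"])
  expect_equal(unname(score), -1.3, tolerance = 1e-12)
  expect_equal(unname(p[1, "A"]), 1 / (1 + exp(1.3)), tolerance = 1e-12)
  expect_lt(abs(unname(p[1, "A"]) - 0.2142), 1e-4)

  # ternary probabilities sum to one
  m3 <- new("MLRModel", classLabels = c("A", "B", "C"),
            coefficients = matrix(rnorm(6), 2))
  p <- predictProba(m3, matrix(rnorm(20), 10, 2))
  expect_equal(unname(rowSums(p)), rep(1, 10), tolerance = 1e-12)
})

test_that("MLR recovers signal, prior, and the Bayes boundary", {
  # identical feature distributions: weights ~ 0, intercept ~ log prior odds
  set.seed(3)
  X <- matrix(rnorm(450), ncol = 3)
  y <- rep(c("A", "B"), c(100, 50))
  m <- fitMLR(X, y, lambda = 1e-4)
  w <- m@coefficients[1, 1:3]
  expect_lt(max(abs(w)), 0.5)
  expect_equal(unname(m@coefficients[1, 4]), log(2), tolerance = 0.5)

  # 1-D two-class problem, means +-3: positive weight for the +3 class,
  # decision boundary near 0
  set.seed(4)
  X <- matrix(c(rnorm(500, 3), rnorm(500, -3)), ncol = 1)
  y <- rep(c("A", "B"), each = 500)
  m <- fitMLR(X, y)
  w <- m@coefficients[1, 1]
  b <- m@coefficients[1, 2]
  expect_gt(w, 0)
  expect_lt(abs(-b / w), 0.5)
})

test_that("our softmax fit agrees with an independent multinomial fitter", {
  skip_if_not_installed("nnet")
  set.seed(5)
  X <- matrix(rnorm(300 * 3), ncol = 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  y <- factor(rep(c("A", "B", "C"), each = 100))
  shift <- model.matrix(~ y - 1)[, 1:2] %*% matrix(c(1, 0, 0.5, -1), 2)
  X[, 1:2] <- X[, 1:2] + shift
  ours <- fitMLR(X, y, lambda = 1e-8)
  ref <- nnet::multinom(y ~ X, trace = FALSE, reltol = 1e-12,
                        maxit = 500)
  pOurs <- predictProba(ours, X)
  pRef <- predict(ref, type = "probs")
  expect_lt(max(abs(pOurs - pRef[, colnames(pOurs)])), 1e-3)
})

test_that("cross-validation is honest: chance at null, high with signal", {
  sv <- binaryCloud(0, seed = 10)
  rep0 <- crossValidate(sv[, statNames()], sv$class_label, folds = 10,
                        seed = 1)
  expect_gt(reportAccuracy(rep0), 0.35)
  expect_lt(reportAccuracy(rep0), 0.65)
  expect_equal(sum(confusionMatrix(rep0)), 300)
  expect_equal(unname(rowSums(confusionMatrix(rep0))), c(150, 150))

  sv <- binaryCloud(3, seed = 11)
  rep3 <- crossValidate(sv[, statNames()], sv$class_label, folds = 10,
                        seed = 1)
  expect_gt(reportAccuracy(rep3), 0.9)
  expect_equal(minClassAccuracy(rep3),
               min(rep3@perClassRecall))
  expect_equal(rep3@tpr, unname(rep3@perClassRecall["A"]))

  # permuted labels collapse accuracy to chance
  set.seed(12)
  svp <- binaryCloud(3, seed = 13)
  svp$class_label <- sample(svp$class_label)
  repP <- crossValidate(svp[, statNames()], svp$class_label, folds = 10,
                        seed = 1)
  expect_lt(reportAccuracy(repP), 0.62)

  # tiny classes are flagged as unstable
  svt <- binaryCloud(3, n = 8, seed = 14)
  expect_warning(
    repT <- crossValidate(svt[, statNames()], svt$class_label, folds = 4,
                          seed = 1),
    "unstable")
  expect_true(repT@flags$unstable)
  expect_error(crossValidate(svt[, statNames()], svt$class_label,
                             folds = 20), "folds")
})

test_that("no test-fold information leaks into fold models", {
  sv <- binaryCloud(1, n = 60, seed = 20)
  X <- as.matrix(sv[, statNames()])
  y <- factor(sv$class_label)
  folds <- 5
  fold <- blinkMux:::stratifiedFolds(y, folds, seed = 2)
  repA <- crossValidate(X, y, folds = folds, seed = 2)
  # fold 1's out-of-fold probabilities must come from a model that saw only
  # the other folds: refit by hand without the fold-1 rows and compare
  tr <- fold != 1
  z <- zscoreFitApply(X[tr, ], X[!tr, ])
  m <- fitMLR(z$train, y[tr], center = z$center, scale = z$scale)
  expect_equal(unname(repA@probabilities[!tr, ]),
               unname(predictProba(m, X[!tr, ])), tolerance = 1e-10)
})

test_that("accuracy rises monotonically with class separation", {
  seps <- c(0, 1, 2, 3, 4)
  acc <- vapply(seps, function(sep) {
    median(vapply(1:3, function(s) {
      sv <- binaryCloud(sep, n = 100, seed = 30 + s)
      reportAccuracy(crossValidate(sv[, statNames()], sv$class_label,
                                   folds = 5, seed = s))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(acc) > -0.03))
  expect_lt(acc[1], 0.62)
  expect_gt(acc[5], 0.93)
})

test_that("thresholding trades retention for accuracy", {
  sv <- binaryCloud(1.5, seed = 40)
  rep1 <- crossValidate(sv[, statNames()], sv$class_label, folds = 10,
                        seed = 3, thresholds = seq(0.5, 0.95, 0.05))
  curve <- reportThresholdCurve(rep1)
  # binary at threshold 0.5: max probability is always >= 0.5
  expect_equal(curve$retention[curve$threshold == 0.5], 1)
  # nested retained sets: retention non-increasing
  expect_true(all(diff(curve$retention) <= 1e-12))
  expect_true(all(diff(curve$retention_A) <= 1e-12))

  # higher-confidence subsets are at least as accurate (median over seeds)
  gains <- vapply(1:10, function(s) {
    sv <- binaryCloud(1.5, n = 100, seed = 50 + s)
    r <- crossValidate(sv[, statNames()], sv$class_label, folds = 5,
                       seed = s, thresholds = c(0.5, 0.9))
    cv <- reportThresholdCurve(r)
    cv$accuracy[2] - cv$accuracy[1]
  }, numeric(1))
  expect_gte(median(gains), 0)

  expect_error(thresholdCurve(matrix(c(0.7, 0.7), 1), factor("A")),
               "sum to 1")
})

test_that("threshold search honors the accuracy target", {
  curve <- data.frame(threshold = c(0.5, 0.6, 0.7),
                      accuracy = c(0.80, 0.85, 0.92),
                      retention = c(1, 0.8, 0.55),
                      n_retained = c(100, 80, 55),
                      retention_A = c(1, 0.85, 0.6),
                      retention_B = c(1, 0.75, 0.5))
  hit <- findThreshold(curve, 0.9)
  expect_true(hit$found)
  expect_equal(hit$threshold, 0.7)
  expect_gte(hit$accuracy, 0.9)
  # the previous grid point fails the target (minimality)
  expect_lt(curve$accuracy[curve$threshold == 0.6], 0.9)

  miss <- findThreshold(curve, 0.99)
  expect_false(miss$found)

  # perfectly separated classes: threshold 0.5 retains everything
  sv <- binaryCloud(8, seed = 60)
  r <- crossValidate(sv[, statNames()], sv$class_label, folds = 10,
                     seed = 4, thresholds = seq(0.5, 0.9, 0.1))
  hit <- findThreshold(reportThresholdCurve(r), 0.99)
  expect_equal(hit$threshold, 0.5)
  expect_equal(hit$retention, 1)

  lop <- curve
  lop$retention_B <- c(1, 0.3, 0.2)
  expect_warning(findThreshold(lop, 0.85), "disproportionately")
})
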