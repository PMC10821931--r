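#' @include AllClasses.R
NULL

asFeatureMatrix <- function(x) {
  if (is.data.frame(x)) {
    keep <- intersect(statNames(), names(x))
    if (!length(keep)) keep <- names(x)[vapply(x, is.numeric, logical(1))]
    x <- as.matrix(x[, keep, drop = FALSE])
  }
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  x
}

#' Z-score normalization fitted on training data
#'
#' Standardizes each statistic to zero mean and unit variance using the
#' training set's moments, and applies the same transform to a test set.
#' Zero-variance statistics carry no information and break the scaling; they
#' are dropped and recorded.
#'
#' @param train training feature matrix or data.frame (statistics columns).
#' @param test optional test features transformed with the training moments.
#' @return List with `train`, `test` (or `NULL`), `center`, `scale` and
#'   `dropped` (names of removed zero-variance columns).
#' @export
zscoreFitApply <- function(train, test = NULL) {
  train <- asFeatureMatrix(train)
  if (!nrow(train)) stop("training set is empty")
  center <- colMeans(train)
  scl <- apply(train, 2, sd)
  dropped <- colnames(train)[!is.finite(scl) | scl == 0]
  keep <- setdiff(colnames(train), dropped)
  if (!length(keep)) stop("all statistics have zero variance")
  center <- center[keep]
  scl <- scl[keep]
  ztr <- scale(train[, keep, drop = FALSE], center = center, scale = scl)
  attr(ztr, "scaled:center") <- NULL
  attr(ztr, "scaled:scale") <- NULL
  zte <- NULL
  if (!is.null(test)) {
    test <- asFeatureMatrix(test)
    zte <- scale(test[, keep, drop = FALSE], center = center, scale = scl)
    attr(zte, "scaled:center") <- NULL
    attr(zte, "scaled:scale") <- NULL
  }
  list(train = ztr, test = zte, center = center, scale = scl,
       dropped = dropped)
}

#' Fit multinomial logistic regression (softmax) for BBM
#'
#' Maximizes the multinomial log-likelihood of the softmax model
#' \deqn{P_j = exp(w_j x + b_j) / \sum_k exp(w_k x + b_k)}
#' over K classes, with the last class as the pivot whose coefficients are
#' fixed at zero (so binary problems reduce to a single logistic
#' discriminant). A small ridge penalty on the weights (not the intercepts)
#' keeps the optimum finite under perfect separation. The optimizer is BFGS
#' with analytic gradient from a zero start, so the fit is deterministic.
#'
#' @param features numeric matrix or statistics data.frame (rows =
#'   molecules). Expected to be z-scored (see [zscoreFitApply()]) unless
#'   `center`/`scale` are supplied for the model record.
#' @param labels class labels (factor or character); factor level order
#'   fixes the pivot (last level).
#' @param lambda ridge penalty (default 1e-6).
#' @param center,scale optional normalization record stored in the model and
#'   applied by [predictProba()].
#' @param dropped names of statistics removed before fitting.
#' @return An [MLRModel-class].
#' @export
fitMLR <- function(features, labels, lambda = 1e-6,
                   center = numeric(0), scale = numeric(0),
                   dropped = character(0)) {
  X <- asFeatureMatrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("at least two classes are required")
  if (any(table(y) < 2L)) stop("every class needs at least two members")
  if (length(y) != nrow(X)) stop("labels must match feature rows")
  K <- nlevels(y)
  p <- ncol(X)
  X1 <- cbind(X, `(Intercept)` = 1)
  Y <- matrix(0, nrow(X), K - 1L)
  yi <- as.integer(y)
  nonPivot <- yi < K
  Y[cbind(which(nonPivot), yi[nonPivot])] <- 1
  penMask <- rep(c(1, 0), c(p, 1))      # no penalty on intercepts

  objective <- function(beta) {
    B <- matrix(beta, K - 1L, p + 1L)
    eta <- X1 %*% t(B)                  # n x (K-1); pivot score 0
    M <- pmax(apply(eta, 1, max), 0)
    logZ <- M + log(exp(-M) + rowSums(exp(eta - M)))
    ll <- sum(eta * Y) - sum(logZ)
    pen <- 0.5 * lambda * sum((B * rep(penMask, each = K - 1L))^2)
    -(ll - pen)
  }
  gradient <- function(beta) {
    B <- matrix(beta, K - 1L, p + 1L)
    eta <- X1 %*% t(B)
    M <- pmax(apply(eta, 1, max), 0)
    logZ <- M + log(exp(-M) + rowSums(exp(eta - M)))
    P <- exp(eta - logZ)
    G <- t(P - Y) %*% X1 + lambda * B * rep(penMask, each = K - 1L)
    as.numeric(G)
  }
  opt <- optim(rep(0, (K - 1L) * (p + 1L)), objective, gradient,
               method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
  B <- matrix(opt$par, K - 1L, p + 1L,
              dimnames = list(levels(y)[-K], colnames(X1)))
  new("MLRModel", classLabels = levels(y), coefficients = B,
      center = center, scale = scale, dropped = dropped,
      lambda = lambda, converged = opt$convergence == 0L)
}

#' Softmax class probabilities
#'
#' Evaluates the fitted model: scores are linear in the (z-scored) blinking
#' statistics with the pivot class fixed at zero, and probabilities are the
#' softmax of the scores, summing to one per molecule. When the model
#' carries a normalization record it is applied to the raw features first.
#'
#' @param model an [MLRModel-class].
#' @param features feature matrix or statistics data.frame.
#' @return Matrix of per-class probabilities (columns in `model@classLabels`
#'   order).
#' @export
predictProba <- function(model, features) {
  X <- asFeatureMatrix(features)
  p <- ncol(model@coefficients) - 1L
  if (length(model@center)) {
    miss <- setdiff(names(model@center), colnames(X))
    if (length(miss))
      stop("features lack statistics required by the model: ",
           paste(miss, collapse = ", "))
    X <- scale(X[, names(model@center), drop = FALSE],
               center = model@center, scale = model@scale)
  } else if (ncol(X) != p) {
    stop("feature dimension does not match the model")
  }
  eta <- cbind(X, 1) %*% t(model@coefficients)
  eta <- cbind(eta, 0)                  # pivot score
  M <- apply(eta, 1, max)
  P <- exp(eta - M)
  P <- P / rowSums(P)
  colnames(P) <- model@classLabels
  rownames(P) <- rownames(X)
  P
}

# stratified fold assignment, deterministic given the seed
stratifiedFolds <- function(labels, folds, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Stratified cross-validated classification
#'
#' Splits the molecules into stratified folds (90/10 train/test at the
#' default 10 folds), and inside each training fold only performs z-score
#' normalization and MLR fitting, so no test-fold information leaks into the
#' model. Out-of-fold probabilities are pooled; the default decision rule is
#' the probability argmax (for binary problems, P > 0.5), ties broken toward
#' the earlier class label.
#'
#' @param features statistics data.frame or matrix (rows = molecules).
#' @param labels class labels.
#' @param folds number of folds (default 10); every class must have at least
#'   `folds` members.
#' @param seed integer seed for the fold assignment.
#' @param lambda ridge penalty for the fold fits.
#' @param thresholds probability thresholds for the retention curve.
#' @return A [ClassificationReport-class]. The overall pooled accuracy,
#'   per-class recalls, their minimum (the minimum classification accuracy),
#'   the confusion matrix (rows = true class), TPR/FPR for binary problems,
#'   and the threshold/accuracy/retention curve are all filled in. Classes
#'   with 10 or fewer members trigger an `unstable` flag and warning, since
#'   accuracy estimates at such sizes are no better than guessing.
#' @export
crossValidate <- function(features, labels, folds = 10, seed = 1,
                          lambda = 1e-6,
                          thresholds = seq(0.5, 0.95, by = 0.05)) {
  y <- factor(labels)
  X <- asFeatureMatrix(features)
  counts <- table(y)
  if (any(counts < folds))
    stop("every class needs at least as many members as folds")
  flags <- list(unstable = FALSE)
  if (any(counts <= 10)) {
    flags$unstable <- TRUE
    warning("classes with n <= 10 molecules: accuracy estimates are unstable")
  }
  fold <- stratifiedFolds(y, folds, seed)
  prob <- matrix(NA_real_, nrow(X), nlevels(y),
                 dimnames = list(NULL, levels(y)))
  for (f in seq_len(folds)) {
    tr <- fold != f
    z <- zscoreFitApply(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
    m <- fitMLR(z$train, y[tr], lambda = lambda,
                center = z$center, scale = z$scale, dropped = z$dropped)
    prob[!tr, ] <- predictProba(m, X[!tr, , drop = FALSE])
  }
  predicted <- factor(levels(y)[max.col(prob, ties.method = "first")],
                      levels = levels(y))
  confusion <- table(true = y, predicted = predicted)
  confusion <- unclass(matrix(confusion, nlevels(y), nlevels(y),
                              dimnames = dimnames(confusion)))
  recall <- diag(confusion) / rowSums(confusion)
  tpr <- fpr <- NA_real_
  if (nlevels(y) == 2L) {
    tpr <- recall[1L]
    fpr <- 1 - recall[2L]
  }
  new("ClassificationReport",
      confusion = confusion,
      accuracy = mean(predicted == y),
      perClassRecall = setNames(as.numeric(recall), levels(y)),
      minClassAccuracy = min(recall),
      tpr = unname(tpr), fpr = unname(fpr),
      thresholdCurve = thresholdCurve(prob, y, thresholds),
      probabilities = prob, labels = y, predicted = predicted,
      flags = flags)
}

#' Accuracy/retention curve under probability thresholding
#'
#' A molecule is retained when its maximum class probability reaches the
#' threshold; "uncertain" molecules below it are discarded. Accuracy is
#' computed over the retained molecules only, and retention (the fraction of
#' molecules kept) is reported overall and within each true class — the
#' per-class values guard against a threshold that empties one class and
#' silently reduces a ternary problem to a binary one.
#'
#' @param probabilities per-class probability matrix (rows sum to 1).
#' @param labels true class labels.
#' @param thresholds increasing probability thresholds.
#' @return data.frame with `threshold`, `accuracy` (NA when nothing is
#'   retained), `retention`, `n_retained` and one `retention_<class>` column
#'   per class.
#' @export
thresholdCurve <- function(probabilities, labels,
                           thresholds = seq(0.5, 0.95, by = 0.05)) {
  y <- factor(labels)
  if (nrow(probabilities) != length(y))
    stop("probabilities and labels must match")
  if (max(abs(rowSums(probabilities) - 1)) > 1e-6)
    stop("probability rows must sum to 1")
  predicted <- factor(colnames(probabilities)[
    max.col(probabilities, ties.method = "first")], levels = levels(y))
  maxP <- apply(probabilities, 1, max)
  rows <- lapply(thresholds, function(th) {
    keep <- maxP >= th
    acc <- if (any(keep)) mean(predicted[keep] == y[keep]) else NA_real_
    perClass <- vapply(levels(y), function(cl)
      mean(keep[y == cl]), numeric(1))
    out <- data.frame(threshold = th, accuracy = acc,
                      retention = mean(keep), n_retained = sum(keep))
    for (cl in levels(y))
      out[[paste0("retention_", cl)]] <- perClass[[cl]]
    out
  })
  do.call(rbind, rows)
}

#' Find the smallest threshold reaching a target accuracy
#'
#' Scans a threshold curve for the minimal threshold whose accuracy over the
#' retained molecules reaches the target, reporting the corresponding overall
#' and per-class data retention. A warning is raised when any class's
#' retention falls below half the overall retention (disproportionate
#' discarding).
#'
#' @param curve data.frame from [thresholdCurve()].
#' @param targetAccuracy accuracy target in (0, 1].
#' @return List with `found` (logical), and when found `threshold`,
#'   `accuracy`, `retention` and `perClassRetention`.
#' @export
findThreshold <- function(curve, targetAccuracy) {
  if (!nrow(curve)) stop("empty threshold curve")
  ok <- which(!is.na(curve$accuracy) & curve$accuracy >= targetAccuracy)
  if (!length(ok)) return(list(found = FALSE, target = targetAccuracy))
  i <- ok[which.min(curve$threshold[ok])]
  perClass <- unlist(curve[i, grep("^retention_", names(curve)),
                           drop = FALSE])
  names(perClass) <- sub("^retention_", "", names(perClass))
  if (length(perClass) && any(perClass < curve$retention[i] / 2))
    warning("some class retains fewer than half the overall retention; ",
            "thresholding is discarding one class disproportionately")
  list(found = TRUE, threshold = curve$threshold[i],
       accuracy = curve$accuracy[i], retention = curve$retention[i],
       perClassRetention = perClass)
}
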