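#' @include AllClasses.R
NULL

# Number of free parameters per family (xmin is fixed at the sample minimum
# or the observation floor, not estimated by likelihood).
familyNPar <- function(family) {
  switch(family,
    lognormal = 2L, weibull = 2L, truncated_power_law = 2L,
    exponential = 1L, power_law = 1L)
}

# CDF of a fitted family at q (unconditional).
familyCDF <- function(q, family, params) {
  switch(family,
    lognormal = pnorm((log10(pmax(q, .Machine$double.xmin)) - params["mu"]) /
                        params["sigma"]) * (q > 0),
    weibull = pweibull(q, shape = params["shape"], scale = params["scale"]),
    exponential = pexp(q, rate = params["rate"]),
    power_law = ifelse(q < params["xmin"], 0,
                       1 - (q / params["xmin"])^(1 - params["alpha"])),
    truncated_power_law = {
      xm <- params["xmin"]; a <- params["alpha"]; lam <- params["cutoffRate"]
      Z <- tplMass(xm, Inf, a, lam)
      vapply(q, function(qi) {
        if (qi <= xm) 0 else min(tplMass(xm, qi, a, lam) / Z, 1)
      }, numeric(1))
    })
}

# integral of t^-alpha * exp(-lambda t) over (lo, hi), computed on the
# log-time scale where the integrand is well behaved for heavy tails.
tplMass <- function(lo, hi, alpha, lambda) {
  f <- function(u) exp((1 - alpha) * u - lambda * exp(u))
  integrate(f, log(lo), if (is.finite(hi)) log(hi) else Inf,
            rel.tol = 1e-9, stop.on.error = FALSE)$value
}

# log density of a fitted family.
familyLogDens <- function(t, family, params) {
  switch(family,
    lognormal = dnorm(log10(t), params["mu"], params["sigma"], log = TRUE) -
      log(t * log(10)),
    weibull = stats::dweibull(t, params["shape"], params["scale"], log = TRUE),
    exponential = stats::dexp(t, params["rate"], log = TRUE),
    power_law = ifelse(t < params["xmin"], -Inf,
                       log(params["alpha"] - 1) - log(params["xmin"]) -
                         params["alpha"] * log(t / params["xmin"])),
    truncated_power_law = {
      Z <- tplMass(params["xmin"], Inf, params["alpha"], params["cutoffRate"])
      ifelse(t < params["xmin"], -Inf,
             -params["alpha"] * log(t) - params["cutoffRate"] * t - log(Z))
    })
}

# sampler for a fitted family (used by the parametric bootstrap).
familySample <- function(n, family, params, floor = 0) {
  par <- as.list(params)
  names(par) <- names(params)
  out <- numeric(0)
  while (length(out) < n) {
    d <- sampleDurations(family, par, max(n - length(out), 16L))
    if (floor > 0) d <- d[d >= floor]
    out <- c(out, d)
  }
  out[seq_len(n)]
}

#' Build the complementary cumulative distribution function of durations
#'
#' Empirical survival P(T >= t) = #\{durations >= t\} / n, evaluated at each
#' observed duration — the standard presentation of heavy-tailed blinking
#' event distributions.
#'
#' @param durations positive event durations in seconds.
#' @param kind optional label recorded with the data (e.g. `"on interval"`).
#' @return data.frame with columns `t` (sorted unique durations) and
#'   `survival`, plus attributes `n` and `kind`.
#' @examples
#' buildCCDF(c(1, 2, 4))
#' @export
buildCCDF <- function(durations, kind = "duration") {
  if (!length(durations)) stop("at least one duration is required")
  if (any(durations <= 0)) stop("durations must be > 0")
  t <- sort(unique(durations))
  surv <- vapply(t, function(ti) mean(durations >= ti), numeric(1))
  out <- data.frame(t = t, survival = surv)
  attr(out, "n") <- length(durations)
  attr(out, "kind") <- kind
  out
}

#' Fit a duration distribution by maximum likelihood
#'
#' Fits one of the mechanistic duration families to pooled event durations.
#' The lognormal fit (log10 parameterization) has the closed form
#' `mu = mean(log10 t)`, `sigma = sqrt(mean((log10 t - mu)^2))` (population
#' denominator); the exponential rate is `1/mean(t)`; the pure power-law
#' exponent is `1 + n / sum(log(t / xmin))` with `xmin` fixed at the smallest
#' duration; Weibull and truncated power-law parameters are found by
#' quasi-Newton maximization of the log-likelihood from moment-based starting
#' values. With `fitFloor > 0` the likelihood conditions on `t >= fitFloor`
#' (durations below one time bin cannot be observed), and the fit is carried
#' out numerically for all families.
#'
#' @param durations positive durations in seconds; all `>= fitFloor`.
#' @param family duration family (see [sampleDurations()]).
#' @param fitFloor lower observation floor in seconds; 0 (default) fits the
#'   unconditional likelihood.
#' @param xmin optional fixed lower cutoff for the power-law families
#'   (default: `max(min(durations), fitFloor)`).
#' @return A [DistFit-class] (without KS results; see [goodnessOfFit()]).
#' @examples
#' d <- sampleDurations("lognormal", list(mu = -1.27, sigma = 2.07),
#'                      5000, seed = 1)
#' fitMLE(d, "lognormal")
#' @export
fitMLE <- function(durations, family, fitFloor = 0, xmin = NULL) {
  if (any(durations <= 0)) stop("durations must be > 0")
  if (fitFloor > 0 && any(durations < fitFloor))
    stop("all durations must be >= fitFloor")
  n <- length(durations)
  if (family %in% c("weibull", "truncated_power_law") && n < 10L)
    stop("at least 10 durations are required for a numerical fit")
  if (n < 2L && family != "exponential")
    stop("too few durations")
  spread <- diff(range(durations))
  if (spread == 0 && family != "exponential")
    stop("identical durations: scale/shape parameters are degenerate")

  lt <- log(durations)
  params <- NULL
  if (fitFloor <= 0) {
    params <- switch(family,
      lognormal = {
        l10 <- log10(durations)
        mu <- mean(l10)
        c(mu = mu, sigma = sqrt(mean((l10 - mu)^2)))
      },
      exponential = c(rate = 1 / mean(durations)),
      power_law = {
        xm <- xmin %||% min(durations)
        c(alpha = 1 + n / sum(log(durations / xm)), xmin = xm)
      },
      NULL)
  } else if (family == "exponential") {
    # memoryless: the floor shifts but does not reshape the distribution
    params <- c(rate = 1 / (mean(durations) - fitFloor))
  }

  if (is.null(params)) {
    params <- numericalMLE(durations, family, fitFloor, xmin)
  }
  ll <- sum(familyLogDens(durations, family, params))
  if (fitFloor > 0)
    ll <- ll - n * log(1 - familyCDF(fitFloor, family, params))
  new("DistFit", family = family, params = params, logLik = ll,
      n = as.integer(n), fitFloor = fitFloor)
}

# numerical (possibly floor-conditioned) MLE for families without closed
# forms, on unconstrained transformed parameters.
numericalMLE <- function(durations, family, fitFloor, xmin) {
  n <- length(durations)
  lt <- log(durations)
  nll <- function(params) {
    v <- suppressWarnings(sum(familyLogDens(durations, family, params)))
    if (fitFloor > 0) {
      p0 <- suppressWarnings(familyCDF(fitFloor, family, params))
      if (!is.finite(p0) || p0 >= 1) return(1e10)
      v <- v - n * log(1 - p0)
    }
    if (!is.finite(v)) 1e10 else -v
  }
  fit <- switch(family,
    weibull = {
      sh0 <- min(max(1.2 / max(sd(lt), 0.05), 0.05), 5)
      start <- c(log(sh0), log(mean(durations)))
      optim(start, function(p)
        nll(c(shape = exp(p[1]), scale = exp(p[2]))),
        method = "BFGS", control = list(maxit = 500))
    },
    lognormal = {
      start <- c(mean(log10(durations)), log(max(sd(log10(durations)), 0.05)))
      optim(start, function(p)
        nll(c(mu = p[1], sigma = exp(p[2]))),
        method = "BFGS", control = list(maxit = 500))
    },
    power_law = {
      xm <- xmin %||% max(min(durations), fitFloor)
      o <- optim(log(0.5), function(p)
        nll(c(alpha = 1 + exp(p), xmin = xm)),
        method = "BFGS", control = list(maxit = 500))
      return(c(alpha = 1 + exp(o$par), xmin = xm))
    },
    truncated_power_law = {
      xm <- xmin %||% max(min(durations), fitFloor)
      o <- optim(c(log(0.5), log(0.1 / median(durations))), function(p)
        nll(c(alpha = 1 + exp(p[1]), xmin = xm, cutoffRate = exp(p[2]))),
        control = list(maxit = 1000))
      return(c(alpha = 1 + exp(o$par[1]), xmin = xm,
               cutoffRate = exp(o$par[2])))
    },
    stop(sprintf("no numerical fit for family '%s'", family)))
  switch(family,
    weibull = c(shape = exp(fit$par[1]), scale = exp(fit$par[2])),
    lognormal = c(mu = fit$par[1], sigma = exp(fit$par[2])))
}

#' Kolmogorov-Smirnov goodness of fit with parametric bootstrap
#'
#' Computes the KS statistic (supremum distance between the empirical CDF of
#' the durations and the fitted CDF, conditioned on the fit floor when one
#' was used) and, when `nBootstrap > 0`, a parametric-bootstrap p-value in
#' which each replicate is re-drawn from the fitted distribution and
#' re-fitted before its KS distance is measured.
#'
#' @param durations the durations the fit was computed from.
#' @param fit a [DistFit-class].
#' @param nBootstrap bootstrap replicates (0 skips the p-value).
#' @param seed integer seed for the bootstrap.
#' @return The fit with `ksD` (and `ksP`) filled in.
#' @export
goodnessOfFit <- function(durations, fit, nBootstrap = 0, seed = 1) {
  if (nBootstrap < 0) stop("'nBootstrap' must be >= 0")
  ksOf <- function(d, f) {
    d <- sort(d[d >= f@fitFloor])
    n <- length(d)
    Ff <- familyCDF(d, f@family, f@params)
    if (f@fitFloor > 0) {
      p0 <- familyCDF(f@fitFloor, f@family, f@params)
      Ff <- (Ff - p0) / (1 - p0)
    }
    max(abs(seq_len(n) / n - Ff), abs((seq_len(n) - 1) / n - Ff))
  }
  fit@ksD <- ksOf(durations, fit)
  if (nBootstrap > 0) {
    set.seed(as.integer(seed))
    n <- fit@n
    dB <- vapply(seq_len(nBootstrap), function(b) {
      x <- familySample(n, fit@family, fit@params, floor = fit@fitFloor)
      fb <- tryCatch(fitMLE(x, fit@family, fitFloor = fit@fitFloor,
                            xmin = unname(fit@params["xmin"])),
                     error = function(e) NULL)
      if (is.null(fb)) NA_real_ else ksOf(x, fb)
    }, numeric(1))
    dB <- dB[!is.na(dB)]
    fit@ksP <- (1 + sum(dB >= fit@ksD)) / (length(dB) + 1)
  }
  fit
}

#' Fit and rank candidate duration families
#'
#' Fits each candidate family by maximum likelihood and ranks the fits.
#' The default criterion is BIC, which reduces to a pure log-likelihood
#' ordering between families with the same number of free parameters and
#' penalizes extra parameters otherwise; `criterion = "loglik"` ranks by
#' log-likelihood alone. KS statistics are reported alongside (and p-values
#' when `nBootstrap > 0`) but are not used for the ranking.
#'
#' @param durations positive durations in seconds.
#' @param families character vector of candidate families.
#' @param fitFloor observation floor passed to [fitMLE()].
#' @param nBootstrap bootstrap replicates for KS p-values (0 to skip).
#' @param seed integer seed.
#' @param criterion `"bic"` (default) or `"loglik"`.
#' @return List of [DistFit-class] objects, best first. Families whose fit
#'   fails (degeneracy) are dropped with a warning.
#' @examples
#' d <- sampleDurations("lognormal", list(mu = -1.27, sigma = 2.07),
#'                      1000, seed = 2)
#' fits <- selectFamily(d, c("lognormal", "exponential", "power_law"))
#' fitFamily(fits[[1]])
#' @export
selectFamily <- function(durations,
                         families = c("lognormal", "weibull", "exponential",
                                      "power_law", "truncated_power_law"),
                         fitFloor = 0, nBootstrap = 0, seed = 1,
                         criterion = c("bic", "loglik")) {
  criterion <- match.arg(criterion)
  if (!length(families)) stop("at least one family is required")
  fits <- list()
  for (fam in families) {
    f <- tryCatch(fitMLE(durations, fam, fitFloor = fitFloor),
                  error = function(e) {
                    warning(sprintf("family '%s' dropped: %s", fam,
                                    conditionMessage(e)), call. = FALSE)
                    NULL
                  })
    if (!is.null(f))
      fits[[fam]] <- goodnessOfFit(durations, f, nBootstrap = nBootstrap,
                                   seed = seed)
  }
  if (!length(fits)) stop("no family could be fitted")
  score <- vapply(fits, function(f) {
    if (criterion == "loglik") -f@logLik
    else -2 * f@logLik + familyNPar(f@family) * log(f@n)
  }, numeric(1))
  fits[order(score)]
}
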