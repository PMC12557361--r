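# Survival-function maximum likelihood for the iMetaD/KTR/EATR hazards.
# With F(t) = int_0^t f dt under the model's averaging mode, the
# log-likelihood of an ensemble with right-censoring is
#   sum_transitions [ log k0 + log f(t_i) - k0 F(t_i) ]
#     - sum_censored [ k0 F(t_max) ] ,
# which reduces to the textbook uncensored form when every run transitions.
# For each gamma the free-k0 MLE is available in closed form,
#   k0(gamma) = n_transitions / sum_all F(t_obs),
# so gamma is profiled on a dense grid (default step 0.01) and then refined
# by bounded local optimization. The likelihood can be extremely flat near
# gamma = 1 when beta*Vmax is small, which is why a grid-first search is used
# and boundary hits are reported rather than silently clipped.

.llFromEval <- function(ev, transitioned, k0) {
  nT <- sum(transitioned)
  if (is.null(k0)) {
    logk0 <- log(nT) - logSumExp(ev$logF)
    list(ll = nT * logk0 + sum(ev$logfObs[transitioned]) - nT,
         k0 = exp(logk0))
  } else {
    if (any(ev$logF > 709)) return(list(ll = -Inf, k0 = k0))
    list(ll = nT * log(k0) + sum(ev$logfObs[transitioned]) -
           k0 * sum(exp(ev$logF)),
         k0 = k0)
  }
}

.gammaGrid <- function(step) seq(0, 1, length.out = round(1 / step) + 1L)

#' Fit a time-dependent rate model to a trajectory ensemble
#'
#' Censoring-aware maximum-likelihood estimation of (k0, gamma) under the
#' EATR, KTR or iMetaD hazard. Either parameter may be fixed by supplying a
#' number, or left free with \code{NULL}; iMetaD is EATR with gamma fixed
#' at 1. gamma is estimated by a dense grid scan (step
#' \code{gammaGridStep}) with closed-form profiling of k0, followed by
#' bounded local refinement. Estimates landing on gamma = 0 or 1 set the
#' \code{boundaryHit} flag. An ensemble carrying no bias leaves gamma
#' unidentifiable: the fit is flagged (not an error) and gamma is NA.
#' All-censored ensembles support fixed-k0 fits only.
#'
#' Bootstrap confidence intervals (\code{nBoot} > 0) resample whole
#' trajectories with replacement -- transition times and bias histories are
#' paired -- refit each replicate, and take 2.5/97.5 percentiles; replicates
#' with zero transitions are skipped and counted. A curvature-based standard
#' error for gamma (from the profile log-likelihood) is reported alongside.
#'
#' @param ens a \linkS4class{TrajectoryEnsemble}.
#' @param family "eatr", "ktr" or "imetad".
#' @param k0 fixed unbiased rate, or NULL (free).
#' @param gamma fixed gamma in [0, 1], or NULL (free).
#' @param averaging "per_trajectory" (default; one hazard per run) or
#'   "ensemble_mean" (runs pooled at each time).
#' @param gammaGridStep grid step for the gamma scan.
#' @param nBoot number of bootstrap replicates (0 = none).
#' @param seed seed for the bootstrap resampling.
#' @param interpolate allow common-grid resampling for ensemble_mean.
#' @return A \linkS4class{RateFit}.
#' @examples
#' sched <- linearRamp(0.015)
#' ens <- sampleTransitionTimes(sched, gammaTrue = 0.8, k0 = 1e-4, n = 50,
#'                              tMax = 1000, seed = 7)
#' fitEATR(ens, k0 = 1e-4)
#' @export
fitRateModel <- function(ens, family = c("eatr", "ktr", "imetad"),
                         k0 = NULL, gamma = NULL,
                         averaging = c("per_trajectory", "ensemble_mean"),
                         gammaGridStep = 0.01, nBoot = 0L, seed = NULL,
                         interpolate = TRUE) {
  family <- match.arg(family)
  averaging <- match.arg(averaging)
  if (family == "imetad") {
    if (!is.null(gamma) && gamma != 1)
      stop("family imetad implies gamma fixed at 1")
    gamma <- 1
  }
  if (!is.null(gamma) && (gamma < 0 || gamma > 1))
    stop("fixed gamma must lie in [0, 1]")
  if (!is.null(k0) && k0 <= 0) stop("fixed k0 must be > 0")
  evalFamily <- if (family == "imetad") "eatr" else family
  obs <- .obsTimes(ens)
  nT <- sum(obs$transitioned)
  nC <- sum(!obs$transitioned)
  if (nT == 0L && is.null(k0))
    stop("estimation error: all runs censored, k0 is unidentifiable; ",
         "fix k0 to fit gamma from the censored survival likelihood")
  maxAbsA <- max(vapply(ens@trajectories, function(tr)
    max(abs(tr@bias)), numeric(1))) * ens@beta
  identifiable <- maxAbsA > 1e-10

  factory <- .modelEvalFactory(ens, evalFamily, averaging, interpolate)
  evalAll <- factory(NULL)

  gammaFree <- is.null(gamma) && identifiable
  if (gammaFree) {
    grid <- .gammaGrid(gammaGridStep)
    evs <- lapply(grid, evalAll)
    lls <- lapply(evs, .llFromEval, transitioned = obs$transitioned, k0 = k0)
    profLL <- vapply(lls, `[[`, numeric(1), "ll")
    profK0 <- vapply(lls, `[[`, numeric(1), "k0")
    iBest <- which.max(profLL)
    lo <- max(0, grid[iBest] - gammaGridStep)
    hi <- min(1, grid[iBest] + gammaGridStep)
    objective <- function(g)
      .llFromEval(evalAll(g), obs$transitioned, k0)$ll
    opt <- optimize(objective, interval = c(lo, hi), maximum = TRUE,
                    tol = 1e-7)
    if (opt$objective >= profLL[iBest]) {
      gHat <- opt$maximum
      llHat <- opt$objective
    } else {
      gHat <- grid[iBest]
      llHat <- profLL[iBest]
    }
    boundary <- FALSE
    if (gHat <= 1e-6 && objective(0) >= llHat - 1e-12) {
      gHat <- 0; llHat <- objective(0); boundary <- TRUE
    } else if (gHat >= 1 - 1e-6 && objective(1) >= llHat - 1e-12) {
      gHat <- 1; llHat <- objective(1); boundary <- TRUE
    }
    fitAtHat <- .llFromEval(evalAll(gHat), obs$transitioned, k0)
    k0Hat <- fitAtHat$k0
    profile <- data.frame(gamma = grid, loglik = profLL, k0 = profK0)
    h <- 0.005
    seGamma <- NA_real_
    if (gHat > h && gHat < 1 - h) {
      d2 <- (objective(gHat + h) - 2 * llHat + objective(gHat - h)) / h^2
      if (is.finite(d2) && d2 < 0) seGamma <- 1 / sqrt(-d2)
    }
  } else {
    gHat <- if (identifiable || !is.null(gamma)) {
      if (is.null(gamma)) NA_real_ else gamma
    } else NA_real_
    gEval <- if (is.na(gHat)) 0 else gHat
    fitAtHat <- .llFromEval(evalAll(gEval), obs$transitioned, k0)
    llHat <- fitAtHat$ll
    k0Hat <- fitAtHat$k0
    profile <- data.frame(gamma = gEval, loglik = llHat, k0 = k0Hat)
    boundary <- FALSE
    seGamma <- NA_real_
    grid <- NULL
  }

  spec <- rateModelSpec(family, averaging,
                        gamma = if (is.null(gamma)) NA_real_ else gamma,
                        k0 = if (is.null(k0)) NA_real_ else k0)
  fit <- new("RateFit", model = spec, k0Hat = k0Hat, gammaHat = gHat,
             loglik = llHat,
             gammaCI = c(NA_real_, NA_real_), k0CI = c(NA_real_, NA_real_),
             seGamma = seGamma, nTransitions = as.integer(nT),
             nCensored = as.integer(nC), converged = is.finite(llHat),
             boundaryHit = boundary,
             gammaIdentifiable = identifiable || !is.null(gamma),
             nBoot = 0L, bootSkipped = 0L, profile = profile)

  if (nBoot > 0L) {
    bt <- .bootstrapRateFit(ens, factory, obs, family = family, k0 = k0,
                            gamma = gamma, identifiable = identifiable,
                            gammaGridStep = gammaGridStep, nBoot = nBoot,
                            seed = seed, averaging = averaging)
    fit@gammaCI <- bt$gammaCI
    fit@k0CI <- bt$k0CI
    fit@nBoot <- as.integer(nBoot)
    fit@bootSkipped <- as.integer(bt$skipped)
  }
  fit
}

# Trajectory-level bootstrap. For per_trajectory averaging the per-run
# log F(gamma) values on the scan grid are cached once, so each replicate is
# a cheap column reduction; for ensemble_mean the pooled hazard changes with
# the resample and each replicate is refit from scratch.
.bootstrapRateFit <- function(ens, factory, obs, family, k0, gamma,
                              identifiable, gammaGridStep, nBoot, seed,
                              averaging) {
  if (!is.null(seed)) set.seed(seed)
  nAll <- length(ens@trajectories)
  grid <- if (is.null(gamma) && identifiable) .gammaGrid(gammaGridStep)
          else (if (is.null(gamma)) 0 else gamma)
  nG <- length(grid)
  gammaBoot <- rep(NA_real_, nBoot)
  k0Boot <- rep(NA_real_, nBoot)
  skipped <- 0L

  cache <- NULL
  if (averaging == "per_trajectory") {
    evalAll <- factory(NULL)
    cache <- lapply(grid, evalAll)    # per gamma: logfObs, logF over all runs
  }
  for (b in seq_len(nBoot)) {
    idx <- sample.int(nAll, nAll, replace = TRUE)
    trB <- obs$transitioned[idx]
    if (!any(trB)) { skipped <- skipped + 1L; next }
    if (!is.null(cache)) {
      lls <- vapply(seq_len(nG), function(gi) {
        ev <- list(logfObs = cache[[gi]]$logfObs[idx],
                   logF = cache[[gi]]$logF[idx])
        .llFromEval(ev, trB, k0)$ll
      }, numeric(1))
      iB <- which.max(lls)
      gB <- grid[iB]
      if (nG > 2L && iB > 1L && iB < nG &&
          is.finite(lls[iB - 1L]) && is.finite(lls[iB + 1L])) {
        den <- lls[iB - 1L] - 2 * lls[iB] + lls[iB + 1L]
        if (den < 0)
          gB <- gB + 0.5 * gammaGridStep *
            (lls[iB - 1L] - lls[iB + 1L]) / den
        gB <- min(max(gB, 0), 1)
      }
      evB <- list(logfObs = cache[[iB]]$logfObs[idx],
                  logF = cache[[iB]]$logF[idx])
      k0Boot[b] <- .llFromEval(evB, trB, k0)$k0
      gammaBoot[b] <- gB
    } else {
      evalSub <- factory(idx)
      lls <- vapply(grid, function(g)
        .llFromEval(evalSub(g), trB, k0)$ll, numeric(1))
      iB <- which.max(lls)
      gammaBoot[b] <- grid[iB]
      k0Boot[b] <- .llFromEval(evalSub(grid[iB]), trB, k0)$k0
    }
  }
  ok <- !is.na(gammaBoot)
  list(gammaCI = unname(quantile(gammaBoot[ok], c(0.025, 0.975),
                                 names = FALSE)),
       k0CI = unname(quantile(k0Boot[ok], c(0.025, 0.975), names = FALSE)),
       skipped = skipped, gammaBoot = gammaBoot, k0Boot = k0Boot)
}

#' @rdname fitRateModel
#' @param ... passed to \code{fitRateModel}.
#' @export
fitEATR <- function(ens, ...) fitRateModel(ens, family = "eatr", ...)

#' @rdname fitRateModel
#' @export
fitKTR <- function(ens, ...) fitRateModel(ens, family = "ktr", ...)

#' @rdname fitRateModel
#' @export
fitIMetaD <- function(ens, ...) fitRateModel(ens, family = "imetad", ...)

#' Fit a model given a RateModelSpec
#' @param ens a \linkS4class{TrajectoryEnsemble}.
#' @param spec a \linkS4class{RateModelSpec}.
#' @param ... passed to \code{\link{fitRateModel}}.
#' @return A \linkS4class{RateFit}.
#' @export
fitModel <- function(ens, spec, ...) {
  fitRateModel(ens, family = spec@family,
               k0 = if (is.na(spec@k0)) NULL else spec@k0,
               gamma = if (is.na(spec@gamma)) NULL else spec@gamma,
               averaging = spec@averaging, ...)
}

#' Bootstrap confidence intervals for an arbitrary rate fit
#'
#' Resamples whole trajectories with replacement (times and bias histories
#' are paired), refits with \code{fitFn}, and returns 2.5/97.5 percentile
#' intervals. Replicates whose resample contains zero transitions are
#' skipped and counted. With a fixed \code{seed} the result is reproducible
#' exactly.
#'
#' @param ens a \linkS4class{TrajectoryEnsemble}.
#' @param fitFn function(ensemble) returning a \linkS4class{RateFit}.
#' @param nBoot number of replicates (>= 100).
#' @param seed RNG seed.
#' @return list(gammaCI, k0CI, nSkipped, gammaBoot, k0Boot).
#' @export
bootstrapCI <- function(ens, fitFn, nBoot = 200L, seed = NULL) {
  if (nBoot < 100L) stop("nBoot must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  nAll <- length(ens@trajectories)
  trans <- .obsTimes(ens)$transitioned
  gammaBoot <- rep(NA_real_, nBoot)
  k0Boot <- rep(NA_real_, nBoot)
  skipped <- 0L
  for (b in seq_len(nBoot)) {
    idx <- sample.int(nAll, nAll, replace = TRUE)
    if (!any(trans[idx])) { skipped <- skipped + 1L; next }
    sub <- trajectoryEnsemble(ens@trajectories[idx], beta = ens@beta,
                              iterationLabel = ens@iterationLabel,
                              pace = ens@pace, timeUnit = ens@timeUnit,
                              energyUnit = ens@energyUnit)
    f <- fitFn(sub)
    gammaBoot[b] <- gammaHat(f)
    k0Boot[b] <- k0Hat(f)
  }
  ok <- !is.na(k0Boot)
  list(gammaCI = unname(quantile(gammaBoot[ok], c(0.025, 0.975),
                                 names = FALSE, na.rm = TRUE)),
       k0CI = unname(quantile(k0Boot[ok], c(0.025, 0.975), names = FALSE)),
       nSkipped = skipped, gammaBoot = gammaBoot, k0Boot = k0Boot)
}

#' Poisson-CDF fit of rescaled transition times with a KS diagnostic
#'
#' Computes the rescaled transition times alpha_i(t_i) * t_i of the
#' transitioned runs, fits their empirical CDF to the Poisson model
#' C(t) = 1 - exp(-t/tau) by least squares on the sorted values, and applies
#' a two-sided Kolmogorov-Smirnov test of the rescaled times against
#' Exponential(tauHat). Because tau is estimated from the same data the
#' plain KS p-value is approximate (conservative); set \code{nBootKS} > 0
#' for a parametric-bootstrap p-value. The maximum-likelihood estimate (the
#' sample mean) is reported as \code{tauMLE}; a warning is emitted when the
#' two estimators disagree by more than 10 percent. Censored runs are
#' excluded -- this estimator, unlike the survival fits, has no censoring
#' term.
#'
#' @param ens a \linkS4class{TrajectoryEnsemble} with >= 3 transitioned runs.
#' @param nBootKS parametric-bootstrap replicates for the KS p-value
#'   (0 = skip).
#' @param seed RNG seed for the bootstrap.
#' @return A \linkS4class{PoissonFit}.
#' @export
fitPoissonCDF <- function(ens, nBootKS = 0L, seed = NULL) {
  perRun <- .perRunTable(ens)
  resc <- perRun$tauAccel[!perRun$censored]
  n <- length(resc)
  if (n < 3L)
    stop("estimation error: need >= 3 transitioned runs for the CDF fit")
  tauLS <- .fitExpCDF(resc)
  tauMLE <- mean(resc)
  if (is.finite(tauLS) && abs(tauLS - tauMLE) > 0.1 * tauMLE)
    warning(sprintf(
      "CDF and MLE characteristic times disagree by > 10%% (%.4g vs %.4g)",
      tauLS, tauMLE), call. = FALSE)
  ks <- suppressWarnings(ks.test(resc, "pexp", rate = 1 / tauLS))
  ksPB <- NA_real_
  if (nBootKS > 0L) {
    if (!is.null(seed)) set.seed(seed)
    statB <- vapply(seq_len(nBootKS), function(b) {
      x <- rexp(n, rate = 1 / tauLS)
      tauB <- .fitExpCDF(x)
      suppressWarnings(ks.test(x, "pexp", rate = 1 / tauB)$statistic)
    }, numeric(1))
    ksPB <- mean(statB >= ks$statistic)
  }
  new("PoissonFit", tauHat = tauLS, tauMLE = tauMLE,
      ksStat = unname(ks$statistic), ksP = ks$p.value, ksPBoot = ksPB,
      rescaledTimes = resc, nTransitions = as.integer(n))
}

# Least squares of the empirical CDF (i/n at the sorted values) against
# 1 - exp(-t/tau), minimized over log tau.
.fitExpCDF <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  emp <- seq_len(n) / n
  sse <- function(logTau) sum((1 - exp(-xs / exp(logTau)) - emp)^2)
  m <- mean(xs)
  if (m <= 0) return(m)
  opt <- optimize(sse, interval = log(m) + c(-6, 6))
  exp(opt$minimum)
}
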