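# 2D double-well Langevin + metadynamics toy system. The potential is
# U(x, y) = barrierHeight * (x^2 - 1)^2 + y^2 / 2 (barrier of exactly
# barrierHeight between the wells at x = -1 and x = +1), the true reaction
# coordinate is x, and hills are deposited along the rotated CV
# s = x cos(theta) + y sin(theta): theta controls RC quality continuously
# from perfect (0 degrees) to orthogonal (90 degrees).

# Per-run seed streams derived from the master seed by a fixed counter
# scheme (independent runs, reproducible ensembles, < 2^31).
.runSeed <- function(seed, i)
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483647)

#' Kramers escape rate of the double well
#'
#' High-barrier overdamped approximation for U(x) = h (x^2 - 1)^2 with unit
#' friction: k0 = sqrt(U''(min) |U''(top)|) / (2 pi) * exp(-beta h), with
#' U''(min) = 8h and U''(top) = -4h.
#'
#' @param barrierHeight barrier h (energy units).
#' @param temperature thermal energy (beta = 1/temperature).
#' @return Escape rate, inverse time units.
#' @export
kramersRate <- function(barrierHeight, temperature = 1) {
  sqrt(8 * barrierHeight * 4 * barrierHeight) / (2 * pi) *
    exp(-barrierHeight / temperature)
}

#' Brute-force unbiased reference rate
#'
#' Runs the unbiased system until \code{nTransitions} first-passage events
#' have been collected (restarting in the reactant well after each) and
#' returns the inverse mean first-passage time with its standard error.
#'
#' @param config a \linkS4class{ToySystemConfig} (bias settings ignored).
#' @param nTransitions events to collect.
#' @param tBudget total simulated-time budget.
#' @param seed RNG seed (default: the config's).
#' @return list(k0, mfpt, se, nEvents).
#' @export
unbiasedRate <- function(config, nTransitions = 50L, tBudget = 1e6,
                         seed = config@seed) {
  set.seed(.runSeed(seed, 0L))
  fpt <- .firstPassageTimesCpp(config@barrierHeight, config@dt,
                               config@temperature, config@commitThreshold,
                               as.integer(nTransitions), tBudget,
                               config@x0, config@y0)
  if (length(fpt) < 2L)
    stop("too few unbiased transitions within the time budget; ",
         "increase tBudget or lower the barrier")
  m <- mean(fpt)
  list(k0 = 1 / m, mfpt = m, se = sd(fpt) / sqrt(length(fpt)) / m^2,
       nEvents = length(fpt))
}

#' Run a metadynamics-biased ensemble on the 2D toy system
#'
#' Integrates \code{nRuns} independent overdamped Langevin trajectories with
#' Gaussian hills deposited every \code{pace} steps along the rotated CV.
#' A run ends at its first passage of x >= commitThreshold (transition time
#' interpolated within the step; bias deposition stops there) or at
#' \code{tMax} (censored). The recorded bias is V(s(t), t), the instantaneous
#' bias experienced at the current CV value -- exactly the quantity the rate
#' models consume.
#'
#' The unbiased reference rate k0Ref is estimated once per configuration:
#' by long unbiased simulation for barriers below 8 kBT, and by the Kramers
#' approximation (\code{\link{kramersRate}}) for barriers of 8 kBT and
#' above, where brute-force sampling becomes wasteful; \code{k0Method}
#' records which was used.
#'
#' @param config a \linkS4class{ToySystemConfig}.
#' @param estimateK0 set FALSE to skip the reference-rate estimate.
#' @return list(ensemble = \linkS4class{TrajectoryEnsemble},
#'   hills = list of \linkS4class{HillSchedule}, k0Ref, k0Method, config).
#' @export
langevinMetad <- function(config, estimateK0 = TRUE) {
  validObject(config)
  beta <- 1 / config@temperature
  trajs <- vector("list", config@nRuns)
  hills <- vector("list", config@nRuns)
  for (i in seq_len(config@nRuns)) {
    set.seed(.runSeed(config@seed, i))
    r <- .langevinRunCpp(config@barrierHeight, config@theta,
                         config@hillHeight, config@hillWidth,
                         config@biasFactor, config@pace, config@dt,
                         config@temperature, config@commitThreshold,
                         config@tMax, config@stride, config@x0, config@y0)
    trajs[[i]] <- biasTrajectory(r$time, r$bias, cv = r$cv,
                                 transitionTime =
                                   if (is.na(r$transition)) numeric()
                                   else r$transition,
                                 label = sprintf("run%03d", i))
    hills[[i]] <- hillSchedule(centers = r$hillCenters,
                               heights = r$hillHeights,
                               widths = rep(config@hillWidth,
                                            length(r$hillTimes)),
                               times = r$hillTimes)
  }
  ens <- trajectoryEnsemble(trajs, beta = beta,
                            iterationLabel = sprintf("theta%g", config@theta),
                            pace = as.numeric(config@pace))
  k0Ref <- NA_real_
  k0Method <- "none"
  if (estimateK0) {
    if (config@barrierHeight >= 8) {
      k0Ref <- kramersRate(config@barrierHeight, config@temperature)
      k0Method <- "kramers"
    } else {
      k0Ref <- unbiasedRate(config)$k0
      k0Method <- "brute_force"
    }
  }
  list(ensemble = ens, hills = hills, k0Ref = k0Ref, k0Method = k0Method,
       config = config)
}

#' Scan the bias-deposition pace at fixed reaction coordinate
#'
#' Re-runs \code{\link{langevinMetad}} at each pace (shared master seed,
#' offset per pace so runs stay independent), fits a fixed-k0 EATR model to
#' each ensemble, and tabulates gamma and the mean accelerated time per
#' pace -- the deposition-frequency robustness diagnostic.
#'
#' @param config a \linkS4class{ToySystemConfig} (its pace is ignored).
#' @param paces integer vector of at least two deposition paces (steps).
#' @param k0 reference rate for the fixed-k0 fits (default: the engine's
#'   k0Ref for this configuration).
#' @param averaging rate-scaling averaging mode for the fits; metadynamics
#'   bias histories fluctuate run-to-run, for which the pooled
#'   "ensemble_mean" convention is the natural choice.
#' @param nBoot bootstrap replicates per fit (0 = no CIs).
#' @param seed master seed (default: the config's).
#' @return data.frame(pace, gammaHat, gammaLo, gammaHi, tauAccelMean,
#'   nTransitions, nCensored), with the reference rate in
#'   \code{attr(, "k0Ref")}.
#' @export
paceScan <- function(config, paces, k0 = NULL,
                     averaging = c("ensemble_mean", "per_trajectory"),
                     nBoot = 100L, seed = config@seed) {
  averaging <- match.arg(averaging)
  if (length(paces) < 2L)
    stop("argument error: supply at least two paces to scan")
  rows <- vector("list", length(paces))
  k0Used <- k0
  for (j in seq_along(paces)) {
    cfg <- config
    cfg@pace <- as.integer(paces[j])
    cfg@seed <- .runSeed(seed, 7919L * j)
    res <- langevinMetad(cfg, estimateK0 = is.null(k0Used) && j == 1L)
    if (is.null(k0Used)) k0Used <- res$k0Ref
    fit <- fitEATR(res$ensemble, k0 = k0Used, averaging = averaging,
                   nBoot = nBoot, seed = .runSeed(seed, 7919L * j + 1L))
    summ <- ensembleSummary(res$ensemble)
    rows[[j]] <- data.frame(
      pace = paces[j], gammaHat = gammaHat(fit),
      gammaLo = gammaCI(fit)[1L], gammaHi = gammaCI(fit)[2L],
      tauAccelMean = meanTauAccel(summ),
      nTransitions = nTransitions(res$ensemble),
      nCensored = nCensored(res$ensemble))
  }
  out <- do.call(rbind, rows)
  attr(out, "k0Ref") <- k0Used
  out
}
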