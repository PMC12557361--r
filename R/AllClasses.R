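#' BiasTrajectory: one biased run's bias time series and transition status
#'
#' Container for a single biased simulation: the recorded time grid, the
#' instantaneous bias potential V(s(t), t) experienced along the biased
#' collective variable, optionally the CV value itself, and the run's
#' transition status. A run either transitioned at \code{transitionTime}
#' (a scalar in (0, tMax]) or is right-censored at \code{tMax}
#' (\code{transitionTime} of length zero).
#'
#' Invariants enforced by the validity method: the time grid is strictly
#' increasing and starts at >= 0, time and bias have equal length >= 2, bias
#' values are finite, and any transition time satisfies 0 < t <= tMax.
#'
#' @slot time numeric, strictly increasing time grid (units arbitrary but
#'   uniform within an ensemble).
#' @slot bias numeric, bias potential at each grid point (energy units).
#' @slot cv numeric, optional CV value at each grid point (length 0 or
#'   \code{length(time)}).
#' @slot transitionTime numeric of length 0 (censored) or 1.
#' @slot tMax numeric, final recorded time.
#' @slot label character run identifier.
#' @exportClass BiasTrajectory
setClass("BiasTrajectory",
  representation(time = "numeric", bias = "numeric", cv = "numeric",
                 transitionTime = "numeric", tMax = "numeric",
                 label = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@time)
    if (n < 2L || length(object@bias) != n)
      msg <- c(msg, "time and bias must have equal length >= 2")
    if (n >= 2L && any(diff(object@time) <= 0))
      msg <- c(msg, "time must be strictly increasing")
    if (n >= 1L && object@time[1L] < 0)
      msg <- c(msg, "time must start at >= 0")
    if (!all(is.finite(object@bias)))
      msg <- c(msg, "bias values must be finite")
    if (length(object@cv) && length(object@cv) != n)
      msg <- c(msg, "cv must be empty or match time in length")
    if (length(object@transitionTime) > 1L)
      msg <- c(msg, "transitionTime must have length 0 or 1")
    if (length(object@transitionTime) == 1L) {
      tt <- object@transitionTime
      if (!is.finite(tt) || tt <= 0 || tt > object@tMax)
        msg <- c(msg, "transitionTime must satisfy 0 < t <= tMax")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a BiasTrajectory
#'
#' @param time,bias,cv numeric vectors (cv optional).
#' @param transitionTime scalar transition time, or `numeric(0)`/`NA` for a
#'   censored run.
#' @param label run identifier.
#' @return A \linkS4class{BiasTrajectory}.
#' @examples
#' biasTrajectory(time = 0:10, bias = 0.2 * (0:10), transitionTime = 8.5)
#' @export
biasTrajectory <- function(time, bias, cv = numeric(),
                           transitionTime = numeric(), label = "") {
  if (length(transitionTime) == 1L && is.na(transitionTime))
    transitionTime <- numeric()
  obj <- new("BiasTrajectory", time = as.numeric(time),
             bias = as.numeric(bias), cv = as.numeric(cv),
             transitionTime = as.numeric(transitionTime),
             tMax = as.numeric(time[length(time)]),
             label = as.character(label))
  if (obj@bias[1L] != 0)
    warning("bias(0) != 0; metadynamics-style runs start with zero bias",
            call. = FALSE)
  obj
}

#' HillSchedule: deposited Gaussian hills
#'
#' Centers, heights, widths and deposition times of the Gaussians making up a
#' metadynamics bias. May have length zero (no bias deposited yet).
#'
#' @slot centers numeric, CV value per hill.
#' @slot heights numeric, energy per hill (after any well-tempered scaling),
#'   all >= 0.
#' @slot widths numeric, CV units, all > 0.
#' @slot times numeric, strictly increasing deposition times.
#' @exportClass HillSchedule
setClass("HillSchedule",
  representation(centers = "numeric", heights = "numeric",
                 widths = "numeric", times = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@times)
    if (length(object@centers) != n || length(object@heights) != n ||
        length(object@widths) != n)
      msg <- c(msg, "centers, heights, widths, times must have equal length")
    if (any(object@heights < 0)) msg <- c(msg, "heights must be >= 0")
    if (any(object@widths <= 0)) msg <- c(msg, "widths must be > 0")
    if (n > 1L && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' Construct a HillSchedule
#' @param centers,heights,widths,times equal-length numeric vectors.
#' @return A \linkS4class{HillSchedule}.
#' @export
hillSchedule <- function(centers = numeric(), heights = numeric(),
                         widths = numeric(), times = numeric()) {
  new("HillSchedule", centers = as.numeric(centers),
      heights = as.numeric(heights), widths = as.numeric(widths),
      times = as.numeric(times))
}

#' TrajectoryEnsemble: a set of biased runs sharing units and beta
#'
#' One RC iteration or one pace setting: an ordered collection of
#' \linkS4class{BiasTrajectory} objects with a common inverse thermal energy
#' beta = 1/(kB T) (in inverse energy units matching the bias) and declared
#' time/energy unit labels.
#'
#' @slot trajectories list of \linkS4class{BiasTrajectory}.
#' @slot beta numeric > 0, inverse thermal energy.
#' @slot iterationLabel character tag (e.g. an RC iteration index).
#' @slot pace numeric, optional bias-deposition pace (NA if unknown).
#' @slot timeUnit,energyUnit character unit labels, declared once per ensemble.
#' @exportClass TrajectoryEnsemble
setClass("TrajectoryEnsemble",
  representation(trajectories = "list", beta = "numeric",
                 iterationLabel = "character", pace = "numeric",
                 timeUnit = "character", energyUnit = "character"),
  validity = function(object) {
    msg <- character()
    if (!length(object@trajectories))
      msg <- c(msg, "at least one trajectory required")
    if (!all(vapply(object@trajectories, is, TRUE, class2 = "BiasTrajectory")))
      msg <- c(msg, "all elements must be BiasTrajectory objects")
    if (length(object@beta) != 1L || !is.finite(object@beta) ||
        object@beta <= 0)
      msg <- c(msg, "beta must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' Construct a TrajectoryEnsemble
#'
#' @param trajectories list of \linkS4class{BiasTrajectory}.
#' @param beta inverse thermal energy 1/(kB T), in inverse energy units
#'   matching the bias.
#' @param iterationLabel optional tag for the RC iteration.
#' @param pace optional deposition pace.
#' @param timeUnit,energyUnit unit labels (purely declarative; no conversion
#'   is ever attempted -- the analysis works in beta*V throughout).
#' @return A \linkS4class{TrajectoryEnsemble}.
#' @export
trajectoryEnsemble <- function(trajectories, beta, iterationLabel = "",
                               pace = NA_real_, timeUnit = "arbitrary",
                               energyUnit = "arbitrary") {
  new("TrajectoryEnsemble", trajectories = trajectories,
      beta = as.numeric(beta), iterationLabel = as.character(iterationLabel),
      pace = as.numeric(pace), timeUnit = timeUnit, energyUnit = energyUnit)
}

#' AccelProfile: time-dependent acceleration quantities of one run
#'
#' The running acceleration factor alpha(t) (the trajectory average of
#' exp(beta*V)), the accelerated time tau_accel(t) = integral of exp(beta*V),
#' and the running bias maximum V_max(t). \code{logTauAccel} carries the
#' log-space accumulation so that profiles remain usable when beta*V exceeds
#' the overflow threshold of exp().
#'
#' @slot time numeric grid inherited from the trajectory.
#' @slot alpha numeric, dimensionless, >= 1 whenever V >= 0.
#' @slot tauAccel numeric, time units, non-decreasing.
#' @slot vmax numeric, running maximum of the bias, non-decreasing.
#' @slot logTauAccel numeric, log(tauAccel).
#' @exportClass AccelProfile
setClass("AccelProfile",
  representation(time = "numeric", alpha = "numeric", tauAccel = "numeric",
                 vmax = "numeric", logTauAccel = "numeric"))

#' EnsembleAccelSummary: acceleration moments of an ensemble
#'
#' Per-ensemble moments over the transitioned runs: the mean accelerated time
#' at transition, the mean acceleration factor, the covariance between biased
#' transition times and acceleration factors, and the iMetaD mean first
#' passage time (the mean of alpha_i(t_i) * t_i, identical to the mean
#' accelerated time). \code{perRun} carries the underlying per-run table
#' including censored runs.
#'
#' @slot meanTauAccel,meanAlpha,covTauAlpha,tauMFPT numeric scalars.
#' @slot nTransitions,nCensored integer counts.
#' @slot covNormalization "population" (denominator N) or "sample" (N-1).
#' @slot perRun data.frame with columns label, t, alpha, tauAccel, vmaxT,
#'   censored.
#' @exportClass EnsembleAccelSummary
setClass("EnsembleAccelSummary",
  representation(meanTauAccel = "numeric", meanAlpha = "numeric",
                 covTauAlpha = "numeric", tauMFPT = "numeric",
                 nTransitions = "integer", nCensored = "integer",
                 covNormalization = "character", perRun = "data.frame"))

#' RateModelSpec: identity of a time-dependent rate model
#'
#' Names one member of the iMetaD/KTR/EATR family, the averaging convention
#' for the rate-scaling function, and whether gamma and k0 are fixed (a
#' number) or free (NA). \code{family = "imetad"} implies gamma fixed at 1.
#'
#' @slot family one of "imetad", "ktr", "eatr".
#' @slot averaging one of "per_trajectory", "ensemble_mean".
#' @slot gamma numeric in [0, 1], or NA when free.
#' @slot k0 numeric > 0, or NA when free.
#' @exportClass RateModelSpec
setClass("RateModelSpec",
  representation(family = "character", averaging = "character",
                 gamma = "numeric", k0 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@family %in% c("imetad", "ktr", "eatr"))
      msg <- c(msg, "family must be imetad, ktr or eatr")
    if (!object@averaging %in% c("per_trajectory", "ensemble_mean"))
      msg <- c(msg, "averaging must be per_trajectory or ensemble_mean")
    if (!is.na(object@gamma) && (object@gamma < 0 || object@gamma > 1))
      msg <- c(msg, "gamma must lie in [0, 1]")
    if (!is.na(object@k0) && object@k0 <= 0)
      msg <- c(msg, "fixed k0 must be > 0")
    if (object@family == "imetad" &&
        (is.na(object@gamma) || object@gamma != 1))
      msg <- c(msg, "family imetad implies gamma fixed at 1")
    if (length(msg)) msg else TRUE
  })

#' Construct a RateModelSpec
#' @param family "eatr", "ktr" or "imetad".
#' @param averaging averaging convention for the rate-scaling function.
#' @param gamma fixed gamma in [0,1], or NA (free).
#' @param k0 fixed unbiased rate, or NA (free).
#' @return A \linkS4class{RateModelSpec}.
#' @export
rateModelSpec <- function(family = c("eatr", "ktr", "imetad"),
                          averaging = c("per_trajectory", "ensemble_mean"),
                          gamma = NA_real_, k0 = NA_real_) {
  family <- match.arg(family)
  if (family == "imetad") {
    if (!is.na(gamma) && gamma != 1)
      stop("family imetad implies gamma fixed at 1")
    gamma <- 1
  }
  new("RateModelSpec", family = family, averaging = match.arg(averaging),
      gamma = as.numeric(gamma), k0 = as.numeric(k0))
}

#' HazardCurve: rate-scaling, cumulative hazard and survival on a grid
#'
#' f(t) is the model's rate-scaling function (dimensionless, >= 1 when V >= 0
#' and gamma >= 0), cumHazard(t) = k0 * integral of f (non-decreasing), and
#' survival(t) = exp(-cumHazard) with S(0) = 1.
#'
#' @slot time,f,cumHazard,survival numeric vectors on a common grid.
#' @slot k0,gamma numeric scalars used to build the curve.
#' @slot family,averaging,label character identity of the curve.
#' @exportClass HazardCurve
setClass("HazardCurve",
  representation(time = "numeric", f = "numeric", cumHazard = "numeric",
                 survival = "numeric", k0 = "numeric", gamma = "numeric",
                 family = "character", averaging = "character",
                 label = "character"))

#' RateFit: a fitted time-dependent rate model
#'
#' Maximum-likelihood estimates of (k0, gamma) under a
#' \linkS4class{RateModelSpec}, with the profile log-likelihood over the
#' gamma grid, optional bootstrap confidence intervals, a curvature-based
#' standard error for gamma, and diagnostic flags. Fixed parameters echo
#' their input values exactly. \code{gammaIdentifiable} is FALSE when the
#' ensemble carries no bias (gamma then drops out of the likelihood);
#' \code{boundaryHit} is TRUE when the estimate lands on 0 or 1.
#'
#' @slot model \linkS4class{RateModelSpec}.
#' @slot k0Hat,gammaHat,loglik numeric scalars.
#' @slot gammaCI,k0CI numeric length-2 (NA when no bootstrap was run).
#' @slot seGamma numeric curvature-based standard error (NA at boundaries).
#' @slot nTransitions,nCensored integer counts.
#' @slot converged,boundaryHit,gammaIdentifiable logical flags.
#' @slot nBoot,bootSkipped integer bootstrap bookkeeping.
#' @slot profile data.frame(gamma, loglik, k0) over the scan grid.
#' @exportClass RateFit
setClass("RateFit",
  representation(model = "RateModelSpec", k0Hat = "numeric",
                 gammaHat = "numeric", loglik = "numeric",
                 gammaCI = "numeric", k0CI = "numeric", seGamma = "numeric",
                 nTransitions = "integer", nCensored = "integer",
                 converged = "logical", boundaryHit = "logical",
                 gammaIdentifiable = "logical", nBoot = "integer",
                 bootSkipped = "integer", profile = "data.frame"))

#' PoissonFit: Poisson-CDF fit of rescaled transition times
#'
#' Least-squares fit of the empirical CDF of the rescaled transition times
#' alpha_i(t_i) * t_i to C(t) = 1 - exp(-t/tau), with a Kolmogorov-Smirnov
#' test of the rescaled times against Exponential(tauHat). \code{tauMLE} is
#' the maximum-likelihood characteristic time (the mean), reported alongside
#' the CDF estimate. The KS p-value uses the fitted tau and is therefore
#' approximate (conservative, Lilliefors-type); a parametric-bootstrap
#' p-value can be requested from \code{\link{fitPoissonCDF}}.
#'
#' @slot tauHat,tauMLE numeric characteristic times (> 0).
#' @slot ksStat,ksP numeric in [0, 1].
#' @slot ksPBoot numeric, parametric-bootstrap p-value (NA unless requested).
#' @slot rescaledTimes numeric, alpha_i(t_i) * t_i per transitioned run.
#' @slot nTransitions integer.
#' @exportClass PoissonFit
setClass("PoissonFit",
  representation(tauHat = "numeric", tauMLE = "numeric", ksStat = "numeric",
                 ksP = "numeric", ksPBoot = "numeric",
                 rescaledTimes = "numeric", nTransitions = "integer"))

#' GammaPrediction: closed-form gamma estimates from ensemble moments
#'
#' Two analytical predictors of gamma from (k0, mean accelerated time, mean
#' acceleration factor): prediction 1 retains the covariance between biased
#' transition times and acceleration factors, prediction 2 drops it. Values
#' falling outside [0, 1] are returned as computed (never clipped) with
#' \code{outOfRange} set -- an out-of-range prediction is itself diagnostic
#' of a misspecified k0.
#'
#' @slot gammaPred1 numeric (NA when the covariance-corrected logarithm is
#'   undefined; see \code{pred1Available}).
#' @slot gammaPred2 numeric.
#' @slot inputsEcho list(k0, meanTauAccel, meanAlpha, covTauAlpha).
#' @slot pred1Available,outOfRange logical flags.
#' @exportClass GammaPrediction
setClass("GammaPrediction",
  representation(gammaPred1 = "numeric", gammaPred2 = "numeric",
                 inputsEcho = "list", pred1Available = "logical",
                 outOfRange = "logical"))

#' BiasSchedule: a prescribed bias-growth protocol V(t)
#'
#' Deterministic bias schedules for the time-rescaling sampler: a linear ramp
#' (V = rate * t), a capped ramp that plateaus at tFill, or a metadynamics
#' hill schedule evaluated at a fixed CV position. V(0) = 0 and V >= 0 for
#' all kinds.
#'
#' @slot kind "linear_ramp", "capped_ramp" or "metad_hills".
#' @slot rate numeric, energy per unit time (ramps).
#' @slot tFill numeric, plateau time (capped ramp).
#' @slot hills \linkS4class{HillSchedule} (metad_hills).
#' @slot evalAt numeric, CV position where hills are evaluated.
#' @exportClass BiasSchedule
setClass("BiasSchedule",
  representation(kind = "character", rate = "numeric", tFill = "numeric",
                 hills = "HillSchedule", evalAt = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("linear_ramp", "capped_ramp", "metad_hills"))
      return("kind must be linear_ramp, capped_ramp or metad_hills")
    if (object@kind != "metad_hills" && object@rate < 0)
      return("ramp rate must be >= 0 (V must be non-negative)")
    if (object@kind == "capped_ramp" &&
        (!is.finite(object@tFill) || object@tFill <= 0))
      return("capped_ramp requires tFill > 0")
    TRUE
  })

#' ToySystemConfig: 2D double-well Langevin + metadynamics configuration
#'
#' Overdamped Langevin dynamics (unit friction) on
#' U(x, y) = barrierHeight * (x^2 - 1)^2 + y^2 / 2, biased by Gaussian hills
#' deposited along the CV s = x cos(theta) + y sin(theta). theta = 0 biases
#' the true reaction coordinate x; theta = 90 biases the orthogonal y.
#'
#' @slot barrierHeight numeric, energy (the barrier is exactly this height).
#' @slot theta numeric, CV rotation angle in degrees, in [0, 90].
#' @slot hillHeight,hillWidth numeric MetaD parameters.
#' @slot biasFactor numeric well-tempered bias factor (Inf = plain MetaD,
#'   the default: the kinetics analysis needs V(t), not a converged FES).
#' @slot pace integer steps between depositions (>= 1).
#' @slot dt numeric integrator step (> 0).
#' @slot temperature numeric, sets beta = 1/temperature.
#' @slot commitThreshold numeric, x value defining the transition (past the
#'   barrier top at x = 0).
#' @slot nRuns integer ensemble size.
#' @slot tMax numeric per-run time budget.
#' @slot stride integer steps between recorded frames.
#' @slot seed integer master seed; per-run streams are derived from it by a
#'   fixed counter scheme.
#' @slot x0,y0 numeric initial condition (reactant well).
#' @exportClass ToySystemConfig
setClass("ToySystemConfig",
  representation(barrierHeight = "numeric", theta = "numeric",
                 hillHeight = "numeric", hillWidth = "numeric",
                 biasFactor = "numeric", pace = "integer", dt = "numeric",
                 temperature = "numeric", commitThreshold = "numeric",
                 nRuns = "integer", tMax = "numeric", stride = "integer",
                 seed = "integer", x0 = "numeric", y0 = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@theta < 0 || object@theta > 90)
      msg <- c(msg, "theta must lie in [0, 90] degrees")
    if (object@pace < 1L) msg <- c(msg, "pace must be >= 1")
    if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
    if (object@commitThreshold <= 0)
      msg <- c(msg, "commitThreshold must lie beyond the barrier top (x = 0)")
    if (object@hillWidth <= 0) msg <- c(msg, "hillWidth must be > 0")
    if (object@temperature <= 0) msg <- c(msg, "temperature must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Construct a ToySystemConfig
#'
#' Defaults describe the reference study conditions used throughout the
#' package's tests: an 8 kBT barrier, hills of height 0.5 and width 0.2
#' deposited every 500 steps of dt = 0.002, 16 runs of at most 600 time
#' units, committed at x = 1.
#'
#' @param barrierHeight,theta,hillHeight,hillWidth,biasFactor,pace,dt
#'   see \linkS4class{ToySystemConfig}.
#' @param temperature,commitThreshold,nRuns,tMax,stride,seed,x0,y0
#'   see \linkS4class{ToySystemConfig}.
#' @return A \linkS4class{ToySystemConfig}.
#' @export
toySystemConfig <- function(barrierHeight = 8, theta = 0, hillHeight = 0.5,
                            hillWidth = 0.2, biasFactor = Inf, pace = 500L,
                            dt = 0.002, temperature = 1, commitThreshold = 1,
                            nRuns = 16L, tMax = 600, stride = 50L, seed = 1L,
                            x0 = -1, y0 = 0) {
  new("ToySystemConfig", barrierHeight = as.numeric(barrierHeight),
      theta = as.numeric(theta), hillHeight = as.numeric(hillHeight),
      hillWidth = as.numeric(hillWidth), biasFactor = as.numeric(biasFactor),
      pace = as.integer(pace), dt = as.numeric(dt),
      temperature = as.numeric(temperature),
      commitThreshold = as.numeric(commitThreshold),
      nRuns = as.integer(nRuns), tMax = as.numeric(tMax),
      stride = as.integer(stride), seed = as.integer(seed),
      x0 = as.numeric(x0), y0 = as.numeric(y0))
}
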