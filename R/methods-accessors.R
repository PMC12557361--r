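#' Accessors for eatr classes
#'
#' Small accessor functions for the package's S4 containers; prefer these
#' over direct slot access.
#'
#' @name accessors
#' @aliases timeGrid biasValues cvValues transitionTime tMax runLabel
#'   isCensored trajectories thermalBeta iterationLabel transitionTimes
#'   nTransitions nCensored alphaValues tauAccel vMax meanTauAccel meanAlpha
#'   covTauAlpha tauMFPT perRunTable gammaHat k0Hat gammaCI k0CI fitLogLik
#'   gammaProfile boundaryHit gammaIdentifiable modelSpec tauHat ksStat
#'   ksPValue rescaledTimes gammaPred1 gammaPred2
NULL

setMethod("timeGrid", "BiasTrajectory", function(x) x@time)
setMethod("biasValues", "BiasTrajectory", function(x) x@bias)
setMethod("cvValues", "BiasTrajectory", function(x) x@cv)
setMethod("transitionTime", "BiasTrajectory", function(x)
  if (length(x@transitionTime)) x@transitionTime else NA_real_)
setMethod("tMax", "BiasTrajectory", function(x) x@tMax)
setMethod("runLabel", "BiasTrajectory", function(x) x@label)
setMethod("isCensored", "BiasTrajectory", function(x)
  length(x@transitionTime) == 0L)

setMethod("trajectories", "TrajectoryEnsemble", function(x) x@trajectories)
setMethod("thermalBeta", "TrajectoryEnsemble", function(x) x@beta)
setMethod("iterationLabel", "TrajectoryEnsemble", function(x) x@iterationLabel)
setMethod("transitionTimes", "TrajectoryEnsemble", function(x)
  vapply(x@trajectories, function(tr) transitionTime(tr), numeric(1)))
setMethod("isCensored", "TrajectoryEnsemble", function(x)
  vapply(x@trajectories, isCensored, logical(1)))
setMethod("nTransitions", "TrajectoryEnsemble", function(x)
  sum(!isCensored(x)))
setMethod("nCensored", "TrajectoryEnsemble", function(x) sum(isCensored(x)))
setMethod("length", "TrajectoryEnsemble", function(x) length(x@trajectories))

#' @rdname accessors
#' @param i trajectory index.
#' @export
setMethod("[[", "TrajectoryEnsemble", function(x, i) x@trajectories[[i]])

setMethod("timeGrid", "AccelProfile", function(x) x@time)
setMethod("alphaValues", "AccelProfile", function(x) x@alpha)
setMethod("tauAccel", "AccelProfile", function(x) x@tauAccel)
setMethod("vMax", "AccelProfile", function(x) x@vmax)

setMethod("meanTauAccel", "EnsembleAccelSummary", function(x) x@meanTauAccel)
setMethod("meanAlpha", "EnsembleAccelSummary", function(x) x@meanAlpha)
setMethod("covTauAlpha", "EnsembleAccelSummary", function(x) x@covTauAlpha)
setMethod("tauMFPT", "EnsembleAccelSummary", function(x) x@tauMFPT)
setMethod("nTransitions", "EnsembleAccelSummary", function(x) x@nTransitions)
setMethod("nCensored", "EnsembleAccelSummary", function(x) x@nCensored)
setMethod("perRunTable", "EnsembleAccelSummary", function(x) x@perRun)

setMethod("gammaHat", "RateFit", function(x) x@gammaHat)
setMethod("k0Hat", "RateFit", function(x) x@k0Hat)
setMethod("gammaCI", "RateFit", function(x) x@gammaCI)
setMethod("k0CI", "RateFit", function(x) x@k0CI)
setMethod("fitLogLik", "RateFit", function(x) x@loglik)
setMethod("gammaProfile", "RateFit", function(x) x@profile)
setMethod("boundaryHit", "RateFit", function(x) x@boundaryHit)
setMethod("gammaIdentifiable", "RateFit", function(x) x@gammaIdentifiable)
setMethod("modelSpec", "RateFit", function(x) x@model)
setMethod("nTransitions", "RateFit", function(x) x@nTransitions)
setMethod("nCensored", "RateFit", function(x) x@nCensored)

setMethod("tauHat", "PoissonFit", function(x) x@tauHat)
setMethod("ksStat", "PoissonFit", function(x) x@ksStat)
setMethod("ksPValue", "PoissonFit", function(x) x@ksP)
setMethod("rescaledTimes", "PoissonFit", function(x) x@rescaledTimes)
setMethod("nTransitions", "PoissonFit", function(x) x@nTransitions)

setMethod("gammaPred1", "GammaPrediction", function(x) x@gammaPred1)
setMethod("gammaPred2", "GammaPrediction", function(x) x@gammaPred2)

#' @rdname accessors
#' @param row.names,optional,... passed on (unused).
#' @export
setMethod("as.data.frame", "AccelProfile",
  function(x, row.names = NULL, optional = FALSE, ...)
    data.frame(time = x@time, alpha = x@alpha, tauAccel = x@tauAccel,
               vmax = x@vmax))

#' @rdname accessors
#' @export
setMethod("as.data.frame", "HazardCurve",
  function(x, row.names = NULL, optional = FALSE, ...)
    data.frame(time = x@time, f = x@f, cumHazard = x@cumHazard,
               survival = x@survival))

#' @rdname accessors
#' @export
setMethod("as.data.frame", "HillSchedule",
  function(x, row.names = NULL, optional = FALSE, ...)
    data.frame(time = x@times, center = x@centers, sigma = x@widths,
               height = x@heights))

setMethod("length", "HillSchedule", function(x) length(x@times))

setMethod("show", "BiasTrajectory", function(object) {
  status <- if (isCensored(object))
    sprintf("censored at t = %g", object@tMax)
  else sprintf("transitioned at t = %g", object@transitionTime)
  cat(sprintf("BiasTrajectory '%s': %d frames on [%g, %g], %s\n",
              object@label, length(object@time), object@time[1L],
              object@tMax, status))
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  cat(sprintf(
    "TrajectoryEnsemble '%s': %d runs (%d transitioned, %d censored), beta = %g\n",
    object@iterationLabel, length(object@trajectories),
    nTransitions(object), nCensored(object), object@beta))
})

setMethod("show", "HillSchedule", function(object) {
  cat(sprintf("HillSchedule: %d hills\n", length(object@times)))
})

setMethod("show", "EnsembleAccelSummary", function(object) {
  cat(sprintf(
    paste0("EnsembleAccelSummary: %d transitioned / %d censored\n",
           "  mean tau_accel = %g, mean alpha = %g, cov(t, alpha) = %g (%s)\n",
           "  tau_MFPT = %g\n"),
    object@nTransitions, object@nCensored, object@meanTauAccel,
    object@meanAlpha, object@covTauAlpha, object@covNormalization,
    object@tauMFPT))
})

setMethod("show", "RateFit", function(object) {
  m <- object@model
  cat(sprintf("RateFit [%s, %s]\n", m@family, m@averaging))
  gtxt <- if (!object@gammaIdentifiable) "unidentifiable (no bias)"
    else sprintf("%.4f%s", object@gammaHat,
                 if (!is.na(m@gamma)) " (fixed)" else
                   if (object@boundaryHit) " (boundary)" else "")
  cat(sprintf("  gamma = %s\n", gtxt))
  if (!any(is.na(object@gammaCI)))
    cat(sprintf("  gamma 95%% CI = [%.4f, %.4f] (bootstrap, n = %d)\n",
                object@gammaCI[1L], object@gammaCI[2L], object@nBoot))
  cat(sprintf("  k0 = %.6g%s\n", object@k0Hat,
              if (!is.na(m@k0)) " (fixed)" else ""))
  cat(sprintf("  loglik = %.4f on %d transitions, %d censored\n",
              object@loglik, object@nTransitions, object@nCensored))
})

setMethod("show", "PoissonFit", function(object) {
  cat(sprintf(
    "PoissonFit: tau = %.6g (CDF), %.6g (MLE); KS D = %.4f, p = %.4g (n = %d)\n",
    object@tauHat, object@tauMLE, object@ksStat, object@ksP,
    object@nTransitions))
})

setMethod("show", "GammaPrediction", function(object) {
  p1 <- if (object@pred1Available) sprintf("%.4f", object@gammaPred1)
    else "unavailable"
  cat(sprintf("GammaPrediction: pred1 = %s, pred2 = %.4f%s\n", p1,
              object@gammaPred2,
              if (object@outOfRange) "  [outside [0,1]: check k0]" else ""))
})

setMethod("show", "HazardCurve", function(object) {
  cat(sprintf(
    "HazardCurve [%s, %s] '%s': %d points, gamma = %g, k0 = %g, S(end) = %.4g\n",
    object@family, object@averaging, object@label, length(object@time),
    object@gamma, object@k0, object@survival[length(object@survival)]))
})

setMethod("show", "ToySystemConfig", function(object) {
  cat(sprintf(
    paste0("ToySystemConfig: barrier %g kBT, theta = %g deg, hills %g x %g",
           " every %d steps\n  dt = %g, T = %g, commit at x = %g, %d runs,",
           " tMax = %g, seed = %d\n"),
    object@barrierHeight, object@theta, object@hillHeight, object@hillWidth,
    object@pace, object@dt, object@temperature, object@commitThreshold,
    object@nRuns, object@tMax, object@seed))
})
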