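#' Time-dependent acceleration profile of one biased run
#'
#' Computes the accelerated time tau_accel(t) = int_0^t exp(beta V(t')) dt'
#' by the trapezoid rule on the exponentiated integrand over the recorded
#' grid, the acceleration factor alpha(t) = tau_accel(t)/t (with alpha(0)
#' defined as exp(beta V(0))), and the running bias maximum V_max(t).
#' Accumulation is done in log space, so profiles remain finite-by-log even
#' when beta*V exceeds the overflow threshold of exp() (tauAccel itself is
#' then Inf, but logTauAccel is exact).
#'
#' @param traj a \linkS4class{BiasTrajectory}.
#' @param beta inverse thermal energy (> 0).
#' @return An \linkS4class{AccelProfile}.
#' @examples
#' tr <- biasTrajectory(time = seq(0, 10, 0.1), bias = rep(0, 101))
#' p <- accelProfile(tr, beta = 1)
#' tail(tauAccel(p), 1)   # 10: zero bias leaves time unstretched
#' @export
accelProfile <- function(traj, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
      beta <= 0)
    stop("parameter error: beta must be a positive scalar")
  if (!all(is.finite(traj@bias)))
    stop("data error: non-finite bias values")
  a <- beta * traj@bias
  L <- logCumTrapzExp(traj@time, a)
  tau <- exp(L)
  alpha <- ifelse(traj@time > 0, tau / traj@time, NA_real_)
  alpha[1L] <- if (traj@time[1L] > 0) tau[1L] / traj@time[1L] else exp(a[1L])
  new("AccelProfile", time = traj@time, alpha = alpha, tauAccel = tau,
      vmax = cummax(traj@bias), logTauAccel = L)
}

# tau_accel of one trajectory evaluated at tStar (log scale); the bias is
# linearly interpolated at tStar and the same trapezoid rule is applied, so
# this value is consistent with the likelihood's cumulative hazard.
.logTauAccelAt <- function(traj, beta, tStar) {
  logTrapzExpAt(traj@time, beta * traj@bias, tStar)
}

.perRunTable <- function(ens) {
  beta <- ens@beta
  rows <- lapply(ens@trajectories, function(tr) {
    cens <- isCensored(tr)
    tObs <- if (cens) tr@tMax else tr@transitionTime
    logTau <- .logTauAccelAt(tr, beta, tObs)
    vmaxT <- max(truncateGrid(tr@time, tr@bias, tObs)$v)
    data.frame(label = tr@label, t = tObs, alpha = exp(logTau) / tObs,
               tauAccel = exp(logTau), vmaxT = vmaxT, censored = cens,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Acceleration summary of an ensemble
#'
#' For every transitioned run i evaluates tau_accel,i(t_i) and
#' alpha_i(t_i) = tau_accel,i(t_i)/t_i at the (possibly interpolated)
#' transition time, and reports the ensemble moments: the mean accelerated
#' time, the mean acceleration factor, the covariance between the biased
#' transition times t_i and alpha_i (population normalization by default),
#' and the iMetaD mean first passage time, the mean of alpha_i(t_i) * t_i --
#' numerically identical to the mean accelerated time. Censored runs appear
#' in the per-run table but do not enter the moments.
#'
#' @param ens a \linkS4class{TrajectoryEnsemble} with at least one
#'   transitioned run.
#' @param covNormalization "population" (denominator N, the convention used
#'   by the closed-form gamma predictors) or "sample" (N - 1).
#' @return An \linkS4class{EnsembleAccelSummary}.
#' @export
ensembleSummary <- function(ens,
                            covNormalization = c("population", "sample")) {
  covNormalization <- match.arg(covNormalization)
  perRun <- .perRunTable(ens)
  tr <- perRun[!perRun$censored, , drop = FALSE]
  if (!nrow(tr))
    stop("estimation error: no transitioned runs; use a censoring-aware ",
         "survival fit (fitEATR/fitKTR with fixed k0) instead of moment ",
         "summaries")
  n <- nrow(tr)
  denom <- if (covNormalization == "population") n else max(n - 1L, 1L)
  covTA <- if (n == 1L) 0 else
    sum((tr$t - mean(tr$t)) * (tr$alpha - mean(tr$alpha))) / denom
  new("EnsembleAccelSummary",
      meanTauAccel = mean(tr$tauAccel), meanAlpha = mean(tr$alpha),
      covTauAlpha = covTA, tauMFPT = mean(tr$alpha * tr$t),
      nTransitions = as.integer(n),
      nCensored = as.integer(sum(perRun$censored)),
      covNormalization = covNormalization, perRun = perRun)
}

#' Per-run acceleration table of an ensemble
#'
#' Convenience wrapper returning (and optionally writing as CSV) the per-run
#' table: run label, observation time, alpha, tau_accel, running bias max at
#' the observation time, and the censored flag.
#'
#' @param ens a \linkS4class{TrajectoryEnsemble}.
#' @param path optional CSV output path.
#' @return The per-run \code{data.frame}, invisibly when \code{path} is given.
#' @export
accelTable <- function(ens, path = NULL) {
  tab <- .perRunTable(ens)
  if (!is.null(path)) {
    write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
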