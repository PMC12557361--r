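# Deterministic bias schedules and the inhomogeneous-Poisson transition-time
# sampler. Transition times are drawn by time rescaling: u ~ Exponential(1),
# then k0 * int_0^t exp(beta * gammaTrue * V(t')) dt' = u is solved for t.
# The cumulative hazard is the same trapezoid quadrature the fitting code
# uses on the emitted grid, so fits see exactly the model that generated the
# data -- the generator/estimator pair is self-validating by construction.

#' Bias schedules for the transition-time sampler
#'
#' \code{linearRamp(rate)} gives V(t) = rate * t; \code{cappedRamp(rate,
#' tFill)} ramps linearly and plateaus at t = tFill (mimicking a bias that
#' has filled the well); \code{metadSchedule(hills, evalAt)} sums deposited
#' Gaussians at a fixed CV position as a function of time. All schedules
#' satisfy V(0) = 0 and V >= 0.
#'
#' @param rate bias growth rate, energy per unit time (>= 0).
#' @param tFill plateau time for the capped ramp.
#' @param hills a \linkS4class{HillSchedule}.
#' @param evalAt CV position at which the hills are evaluated.
#' @return A \linkS4class{BiasSchedule}.
#' @export
linearRamp <- function(rate) {
  new("BiasSchedule", kind = "linear_ramp", rate = as.numeric(rate),
      tFill = Inf, hills = hillSchedule(), evalAt = 0)
}

#' @rdname linearRamp
#' @export
cappedRamp <- function(rate, tFill) {
  new("BiasSchedule", kind = "capped_ramp", rate = as.numeric(rate),
      tFill = as.numeric(tFill), hills = hillSchedule(), evalAt = 0)
}

#' @rdname linearRamp
#' @export
metadSchedule <- function(hills, evalAt = 0) {
  new("BiasSchedule", kind = "metad_hills", rate = 0, tFill = Inf,
      hills = hills, evalAt = as.numeric(evalAt))
}

#' Evaluate a bias schedule
#' @param schedule a \linkS4class{BiasSchedule}.
#' @param t time(s) at which to evaluate V.
#' @return V(t), energy units.
#' @export
evaluateSchedule <- function(schedule, t) {
  switch(schedule@kind,
    linear_ramp = schedule@rate * t,
    capped_ramp = schedule@rate * pmin(t, schedule@tFill),
    metad_hills = {
      h <- schedule@hills
      vapply(t, function(tt) {
        on <- h@times <= tt
        if (!any(on)) return(0)
        sum(h@heights[on] *
              exp(-(schedule@evalAt - h@centers[on])^2 /
                    (2 * h@widths[on]^2)))
      }, numeric(1))
    })
}

#' Sample transition times from a prescribed biased hazard
#'
#' Generates an ensemble of runs whose transition times follow the
#' time-dependent rate k(t) = k0 * exp(beta * gammaTrue * V(t)) for the
#' given bias schedule, by inverting the cumulative hazard (time rescaling):
#' each run draws u ~ Exponential(1) and solves
#' k0 * int_0^t exp(beta gammaTrue V) dt' = u for t on the recording grid
#' (root-finding within the bracketing grid interval, relative tolerance
#' 1e-9). Runs whose hazard does not reach u by \code{tMax} are
#' right-censored there.
#'
#' Each emitted \linkS4class{BiasTrajectory} records the full V(t) on a
#' uniform grid -- exactly what real biased data would contain. Downstream
#' fits use gamma as the exponent on this full V, so ensembles built with
#' \code{gammaTrue} < 1 emulate imperfect reaction coordinates where only a
#' fraction of the applied bias accelerates the transition;
#' \code{gammaTrue} = 0 gives plain Exponential(k0) times with an
#' ineffective bias on record.
#'
#' @param schedule a \linkS4class{BiasSchedule}.
#' @param gammaTrue true bias effectiveness in [0, 1].
#' @param k0 true unbiased rate (> 0).
#' @param n number of runs (>= 1).
#' @param tMax censoring horizon.
#' @param beta inverse thermal energy (default 1; the schedule is then read
#'   directly in beta*V units).
#' @param seed RNG seed (NULL = current RNG state).
#' @param gridN number of uniform grid points on [0, tMax].
#' @param iterationLabel ensemble tag.
#' @return A \linkS4class{TrajectoryEnsemble}.
#' @examples
#' ens <- sampleTransitionTimes(linearRamp(0.015), gammaTrue = 1, k0 = 1e-4,
#'                              n = 20, tMax = 1000, seed = 1)
#' nTransitions(ens)
#' @export
sampleTransitionTimes <- function(schedule, gammaTrue, k0, n, tMax,
                                  beta = 1, seed = NULL, gridN = 501L,
                                  iterationLabel = "") {
  if (gammaTrue < 0 || gammaTrue > 1) stop("gammaTrue must lie in [0, 1]")
  if (k0 <= 0) stop("k0 must be > 0")
  if (n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, tMax, length.out = gridN)
  V <- evaluateSchedule(schedule, tt)
  if (any(V < 0)) stop("schedule must be non-negative")
  a <- beta * gammaTrue * V
  if (max(a) > 700)
    stop("beta*gamma*V exceeds 700 on the grid; rescale the schedule ",
         "(transitions this deep into the ramp are instantaneous anyway)")
  ea <- exp(a)
  H <- k0 * c(0, cumsum(diff(tt) / 2 * (ea[-gridN] + ea[-1L])))
  u <- rexp(n)
  trajs <- vector("list", n)
  for (i in seq_len(n)) {
    if (H[gridN] < u[i]) {
      trajs[[i]] <- biasTrajectory(tt, V, label = sprintf("run%03d", i))
      next
    }
    j <- which(H >= u[i])[1L]       # H[j-1] < u <= H[j]
    t0 <- tt[j - 1L]; t1 <- tt[j]
    # partial trapezoid with the bias (hence the exponent) linearly
    # interpolated inside the interval -- identical to the fitting rule
    part <- function(ts) {
      aS <- a[j - 1L] + (ts - t0) / (t1 - t0) * (a[j] - a[j - 1L])
      H[j - 1L] + k0 * (ts - t0) / 2 * (ea[j - 1L] + exp(aS)) - u[i]
    }
    tStar <- uniroot(part, c(t0, t1), tol = 1e-9 * max(t1, 1))$root
    g <- truncateGrid(tt, V, tStar)
    trajs[[i]] <- biasTrajectory(g$t, g$v, transitionTime = tStar,
                                 label = sprintf("run%03d", i))
  }
  trajectoryEnsemble(trajs, beta = beta, iterationLabel = iterationLabel)
}
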