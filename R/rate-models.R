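# The iMetaD/KTR/EATR family as integrable hazards. All three share the form
# k(t) = k0 * f(t):
#   EATR:   f from exp(beta*gamma*V(t))        (instantaneous bias)
#   KTR:    f from exp(beta*gamma*Vmax(t))     (running bias maximum)
#   iMetaD: EATR with gamma = 1
# "per_trajectory" averaging keeps one hazard per run (a well-defined
# likelihood for heterogeneous bias histories, the default); "ensemble_mean"
# pools runs at each time, holding a run's bias frozen at its last recorded
# value after it ends (bias deposition stops at transition).

.commonGrid <- function(ens, interpolate = TRUE) {
  grids <- lapply(ens@trajectories, function(tr) tr@time)
  if (length(grids) == 1L ||
      all(vapply(grids[-1L], identical, TRUE, y = grids[[1L]])))
    return(grids[[1L]])
  if (!interpolate)
    stop("grid error: ensemble_mean averaging needs a common time grid; ",
         "set interpolate = TRUE to resample")
  n <- max(lengths(grids))
  seq(0, max(vapply(grids, max, numeric(1))), length.out = n)
}

# Runs resampled to a common grid, linear in V (not in exp(beta*V)), frozen
# at their last value beyond each run's end. For KTR the running max is taken
# on the native grid first, then resampled.
.resampledBias <- function(ens, grid, runningMax = FALSE) {
  t(vapply(ens@trajectories, function(tr) {
    v <- if (runningMax) cummax(tr@bias) else tr@bias
    approx(tr@time, v, xout = grid, rule = 2)$y
  }, numeric(length(grid))))
}

.obsTimes <- function(ens) {
  cens <- isCensored(ens)
  tObs <- vapply(ens@trajectories, function(tr)
    if (isCensored(tr)) tr@tMax else tr@transitionTime, numeric(1))
  list(tObs = tObs, transitioned = !cens)
}

# Factory for likelihood evaluations. Returns function(subset) ->
# function(gamma) -> list(logfObs, logF) where, for every run in `subset`,
# logF is log int_0^{tObs} f dt and logfObs is log f(tObs).
.modelEvalFactory <- function(ens, family = c("eatr", "ktr"),
                              averaging = c("per_trajectory",
                                            "ensemble_mean"),
                              interpolate = TRUE) {
  family <- match.arg(family)
  averaging <- match.arg(averaging)
  beta <- ens@beta
  obs <- .obsTimes(ens)
  nAll <- length(ens@trajectories)

  if (averaging == "per_trajectory") {
    parts <- lapply(seq_len(nAll), function(i) {
      tr <- ens@trajectories[[i]]
      g <- truncateGrid(tr@time, tr@bias, obs$tObs[i])
      v <- if (family == "ktr") cummax(g$v) else g$v
      list(a = beta * v, logw = log(trapWeights(g$t)),
           aEnd = beta * v[length(v)])
    })
    aEnd <- vapply(parts, `[[`, numeric(1), "aEnd")
    maxA <- max(vapply(parts, function(p) max(p$a), numeric(1)))
    function(subset = NULL) {
      idx <- if (is.null(subset)) seq_len(nAll) else subset
      aAll <- unlist(lapply(parts[idx], `[[`, "a"), use.names = FALSE)
      logwAll <- unlist(lapply(parts[idx], `[[`, "logw"), use.names = FALSE)
      grp <- rep.int(seq_along(idx),
                     vapply(parts[idx], function(p) length(p$a), integer(1)))
      splitIdx <- NULL
      function(gamma) {
        s <- gamma * aAll + logwAll
        if (gamma * maxA < 700) {
          logF <- log(as.numeric(rowsum(exp(s), grp, reorder = TRUE)))
        } else {
          if (is.null(splitIdx))
            splitIdx <<- split(seq_along(grp), grp)
          logF <- vapply(splitIdx, function(ii) logSumExp(s[ii]), numeric(1))
        }
        list(logfObs = gamma * aEnd[idx], logF = logF)
      }
    }
  } else {
    grid <- .commonGrid(ens, interpolate)
    vmat <- .resampledBias(ens, grid, runningMax = (family == "ktr"))
    function(subset = NULL) {
      idx <- if (is.null(subset)) seq_len(nAll) else subset
      vm <- vmat[idx, , drop = FALSE]
      function(gamma) {
        am <- gamma * beta * vm
        logf <- if (family == "ktr") {
          gamma * beta * colMeans(vm)
        } else {
          m <- apply(am, 2L, max)
          m + log(colMeans(exp(sweep(am, 2L, m))))
        }
        logF <- vapply(idx, function(ii) NA_real_, numeric(1))
        logfObs <- logF
        for (j in seq_along(idx)) {
          tO <- obs$tObs[idx[j]]
          logF[j] <- logTrapzExpAt(grid, logf, tO)
          logfObs[j] <- approx(grid, logf, xout = tO, rule = 2)$y
        }
        list(logfObs = logfObs, logF = logF)
      }
    }
  }
}

.makeHazardCurve <- function(time, logf, k0, gamma, family, averaging,
                             label) {
  cumH <- k0 * exp(logCumTrapzExp(time, logf))
  new("HazardCurve", time = time, f = exp(logf), cumHazard = cumH,
      survival = exp(-cumH), k0 = k0, gamma = gamma, family = family,
      averaging = averaging, label = label)
}

#' EATR rate-scaling and hazard curves
#'
#' Builds the EATR hazard, f(t) = exp(beta * gamma * V(t)). With
#' \code{averaging = "per_trajectory"} one \linkS4class{HazardCurve} per run
#' is returned (a list), each on the run's own grid, with cumulative hazard
#' k0 * int_0^t exp(beta gamma V_i) dt' -- at gamma = 1 this is exactly
#' k0 * tau_accel,i(t), the iMetaD accelerated time. With
#' \code{averaging = "ensemble_mean"} runs are pooled on a common grid,
#' f(t) = mean_i exp(beta gamma V_i(t)), with each run's bias frozen at its
#' last recorded value after the run ends.
#'
#' @param ens a \linkS4class{TrajectoryEnsemble}.
#' @param gamma dimensionless bias-effectiveness in [0, 1].
#' @param k0 unbiased rate used for the cumulative hazard and survival.
#' @param averaging "per_trajectory" or "ensemble_mean".
#' @param interpolate allow resampling to a common grid for ensemble_mean;
#'   if FALSE and the grids differ, a grid error is raised.
#' @return A list of \linkS4class{HazardCurve} (per_trajectory) or a single
#'   pooled \linkS4class{HazardCurve} (ensemble_mean).
#' @export
fEATR <- function(ens, gamma, k0 = 1,
                  averaging = c("per_trajectory", "ensemble_mean"),
                  interpolate = TRUE) {
  .fFamily(ens, gamma, k0, match.arg(averaging), "eatr", interpolate)
}

#' KTR rate-scaling and hazard curves
#'
#' As \code{\link{fEATR}} but with the running bias maximum in place of the
#' instantaneous bias: f(t) = exp(beta * gamma * Vmax(t)) per run, or
#' exp(beta * gamma * mean_i Vmax_i(t)) when pooled. For strictly
#' non-decreasing bias (typical metadynamics before transition) KTR and EATR
#' coincide; whenever the bias dips, KTR dominates.
#'
#' @inheritParams fEATR
#' @return As \code{\link{fEATR}}.
#' @export
fKTR <- function(ens, gamma, k0 = 1,
                 averaging = c("per_trajectory", "ensemble_mean"),
                 interpolate = TRUE) {
  .fFamily(ens, gamma, k0, match.arg(averaging), "ktr", interpolate)
}

.fFamily <- function(ens, gamma, k0, averaging, family, interpolate) {
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1)
    stop("gamma must lie in [0, 1]")
  beta <- ens@beta
  if (averaging == "per_trajectory") {
    curves <- lapply(ens@trajectories, function(tr) {
      v <- if (family == "ktr") cummax(tr@bias) else tr@bias
      .makeHazardCurve(tr@time, gamma * beta * v, k0, gamma, family,
                       averaging, tr@label)
    })
    names(curves) <- vapply(ens@trajectories, runLabel, character(1))
    curves
  } else {
    grid <- .commonGrid(ens, interpolate)
    vmat <- .resampledBias(ens, grid, runningMax = (family == "ktr"))
    logf <- if (family == "ktr") {
      gamma * beta * colMeans(vmat)
    } else {
      am <- gamma * beta * vmat
      m <- apply(am, 2L, max)
      m + log(colMeans(exp(sweep(am, 2L, m))))
    }
    .makeHazardCurve(grid, logf, k0, gamma, family, averaging,
                     ens@iterationLabel)
  }
}

#' Survival probability at a time point
#'
#' Interpolates S(t) = exp(-cumHazard(t)) on a \linkS4class{HazardCurve}
#' (linear interpolation of the cumulative hazard).
#'
#' @param curve a \linkS4class{HazardCurve}.
#' @param t evaluation time(s), within the curve's grid span.
#' @return Survival probabilities in (0, 1].
#' @export
survivalAt <- function(curve, t) {
  if (any(t < 0)) stop("domain error: t must be >= 0")
  if (any(t > max(curve@time)))
    stop("domain error: t beyond the curve's grid span")
  ch <- approx(curve@time, curve@cumHazard, xout = t, rule = 2)$y
  exp(-ch)
}
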