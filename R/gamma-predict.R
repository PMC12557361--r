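#' Closed-form gamma predictors from ensemble moments
#'
#' Evaluates the two analytical approximations that link gamma to the mean
#' accelerated time, given a known (or assumed) unbiased rate k0:
#' \deqn{\gamma \approx 1 - \log(k_0(\bar\tau_{accel} -
#'   \mathrm{cov}(\tau', \alpha))) / \log(\bar\alpha)}{
#'   gamma ~ 1 - log(k0 (tauAccel - cov(t, alpha))) / log(meanAlpha)}
#' (prediction 1, with the covariance between biased transition times and
#' acceleration factors) and the reduced form dropping the covariance
#' (prediction 2). The mean acceleration factor is taken as the mean of
#' alpha_i(t_i) over transitioned runs. Values outside [0, 1] are returned
#' as computed with the \code{outOfRange} flag set -- they signal a
#' misspecified k0 and are deliberately not clipped.
#'
#' @param x an \linkS4class{EnsembleAccelSummary} or a
#'   \linkS4class{TrajectoryEnsemble} (summarized internally).
#' @param k0 unbiased rate constant (> 0).
#' @param covNormalization forwarded to \code{\link{ensembleSummary}} when
#'   \code{x} is an ensemble.
#' @return A \linkS4class{GammaPrediction}.
#' @examples
#' s <- new("EnsembleAccelSummary", meanTauAccel = 1e4, meanAlpha = 100,
#'          covTauAlpha = 0, tauMFPT = 1e4, nTransitions = 10L,
#'          nCensored = 0L, covNormalization = "population",
#'          perRun = data.frame())
#' gammaPred2(predictGamma(s, k0 = 1e-3))   # 1 - log(10)/log(100) = 0.5
#' @export
predictGamma <- function(x, k0,
                         covNormalization = c("population", "sample")) {
  if (is(x, "TrajectoryEnsemble"))
    x <- ensembleSummary(x, covNormalization = match.arg(covNormalization))
  if (!is(x, "EnsembleAccelSummary"))
    stop("x must be a TrajectoryEnsemble or EnsembleAccelSummary")
  if (!is.numeric(k0) || k0 <= 0) stop("k0 must be > 0")
  aBar <- x@meanAlpha
  tauBar <- x@meanTauAccel
  covTA <- x@covTauAlpha
  if (!is.finite(aBar) || aBar <= 1)
    stop("undefined-predictor error: mean alpha <= 1 (no effective bias), ",
         "log(mean alpha) is not positive")
  pred2 <- 1 - log(k0 * tauBar) / log(aBar)
  p1Avail <- (tauBar - covTA) > 0
  pred1 <- if (p1Avail) 1 - log(k0 * (tauBar - covTA)) / log(aBar)
           else NA_real_
  oor <- (pred2 < 0 || pred2 > 1) ||
    (p1Avail && (pred1 < 0 || pred1 > 1))
  new("GammaPrediction", gammaPred1 = pred1, gammaPred2 = pred2,
      inputsEcho = list(k0 = k0, meanTauAccel = tauBar, meanAlpha = aBar,
                        covTauAlpha = covTA),
      pred1Available = p1Avail, outOfRange = oor)
}

#' Compare closed-form gamma predictions with a survival fit
#'
#' Evaluates both moment-based predictors on an ensemble and sets them
#' against the gamma estimate of a fixed-k0 EATR fit of the same ensemble
#' (the fit's fixed k0 is reused for the predictors). The
#' \code{covNonNegligible} flag is raised when the two predictions differ by
#' more than 0.05, i.e. when dropping the covariance term is not innocuous.
#'
#' @param ens a \linkS4class{TrajectoryEnsemble}.
#' @param fit a fixed-k0 \linkS4class{RateFit} for the same ensemble.
#' @return A one-row \code{data.frame} with columns gammaFit, gammaPred1,
#'   gammaPred2, gapPred1, gapPred2, covNonNegligible, pred1Available.
#' @export
comparePredictions <- function(ens, fit) {
  if (!is(fit, "RateFit")) stop("fit must be a RateFit")
  if (is.na(fit@model@k0))
    stop("fit must have k0 fixed (the predictors require a known k0)")
  pred <- predictGamma(ens, k0 = fit@model@k0)
  gf <- fit@gammaHat
  p1 <- pred@gammaPred1
  p2 <- pred@gammaPred2
  data.frame(
    gammaFit = gf, gammaPred1 = p1, gammaPred2 = p2,
    gapPred1 = abs(p1 - gf), gapPred2 = abs(p2 - gf),
    covNonNegligible = isTRUE(abs(p1 - p2) > 0.05),
    pred1Available = pred@pred1Available)
}
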