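test_that("unbiased ensembles give the exponential-MLE k0 and flag gamma", {
  set.seed(5)
  ens <- mkUnbiasedEnsemble(rexp(200, 1e-3))
  fit <- fitEATR(ens)
  expect_false(gammaIdentifiable(fit))
  expect_true(is.na(gammaHat(fit)))
  expect_equal(k0Hat(fit), 1e-3, tolerance = 0.15)
  # closed form: n / sum(t_i) -- every run transitioned, F truncates at t_i
  expect_equal(k0Hat(fit), length(ens) / sum(transitionTimes(ens)),
               tolerance = 1e-10)
})

test_that("fixed-k0 EATR recovers gamma from its own generating hazard", {
  ens <- sampleTransitionTimes(linearRamp(0.015), gammaTrue = 0.8,
                               k0 = 1e-4, n = 100, tMax = 1000, seed = 31)
  fit <- fitEATR(ens, k0 = 1e-4, nBoot = 200, seed = 1)
  expect_gte(gammaCI(fit)[2], 0.8 - 1e-9)
  expect_lte(gammaCI(fit)[1], 0.8 + 1e-9)
  expect_equal(gammaHat(fit), 0.8, tolerance = 0.1)
  expect_false(boundaryHit(fit))
  expect_true(is.finite(fit@seGamma))
})

test_that("gamma = 1 free-k0 fit inverts the mean rescaled time", {
  ens <- sampleTransitionTimes(linearRamp(0.015), 1, 1e-4, n = 200,
                               tMax = 1000, seed = 4)
  expect_equal(nCensored(ens), 0L)
  fit <- fitEATR(ens, gamma = 1)
  s <- ensembleSummary(ens)
  expect_equal(k0Hat(fit), 1 / meanTauAccel(s), tolerance = 1e-10)
  # cross-check against the Poisson-CDF characteristic time (within 5%)
  pf <- suppressWarnings(fitPoissonCDF(ens))
  expect_equal(k0Hat(fit), 1 / tauHat(pf), tolerance = 0.05)
})

test_that("KTR matches EATR on monotone schedules and finds the null", {
  ens <- sampleTransitionTimes(linearRamp(0.015), 0.6, 1e-4, n = 80,
                               tMax = 1000, seed = 13)
  fe <- fitEATR(ens, k0 = 1e-4)
  fk <- fitKTR(ens, k0 = 1e-4)
  expect_equal(gammaHat(fk), gammaHat(fe), tolerance = 1e-4)

  ens0 <- sampleTransitionTimes(linearRamp(0.015), 0, 1e-4, n = 200,
                                tMax = 1000, seed = 17)
  fk0 <- fitKTR(ens0, k0 = 1e-4)
  expect_lte(gammaHat(fk0), 0.05)

  # fully fixed fit: no free parameters, finite loglik only
  ff <- fitKTR(ens, k0 = 1e-4, gamma = 1)
  expect_true(is.finite(fitLogLik(ff)))
  expect_equal(gammaHat(ff), 1)
  expect_equal(k0Hat(ff), 1e-4)
})

test_that("profile likelihood over gamma is unimodal on ramp schedules", {
  ens <- sampleTransitionTimes(linearRamp(0.015), 0.5, 1e-4, n = 100,
                               tMax = 1000, seed = 23)
  prof <- gammaProfile(fitEATR(ens, k0 = 1e-4))
  d <- diff(prof$loglik)
  signChanges <- sum(diff(sign(d[d != 0])) != 0)
  expect_lte(signChanges, 1L)
})

test_that("fixing k0 lowers the variance of the gamma estimate", {
  gFixed <- gFree <- numeric(12)
  for (i in 1:12) {
    ens <- sampleTransitionTimes(linearRamp(0.015), 0.5, 1e-4, n = 100,
                                 tMax = 1000, seed = 300 + i)
    gFixed[i] <- gammaHat(fitEATR(ens, k0 = 1e-4))
    gFree[i] <- gammaHat(fitEATR(ens))
  }
  expect_lt(var(gFixed), var(gFree))
})

test_that("Poisson-CDF fit recovers tau and its KS test calibrates", {
  set.seed(6)
  pf <- suppressWarnings(fitPoissonCDF(mkUnbiasedEnsemble(rexp(500, 1 / 100))))
  expect_equal(tauHat(pf), 100, tolerance = 0.1)
  expect_gt(ksPValue(pf), 0.05)
  expect_true(ksStat(pf) >= 0 && ksStat(pf) <= 1)

  # parametric-bootstrap p-value is returned on request and reproducible
  ensB <- mkUnbiasedEnsemble(rexp(80, 1 / 50))
  pfb <- suppressWarnings(fitPoissonCDF(ensB, nBootKS = 100, seed = 2))
  pfb2 <- suppressWarnings(fitPoissonCDF(ensB, nBootKS = 100, seed = 2))
  expect_true(pfb@ksPBoot >= 0 && pfb@ksPBoot <= 1)
  expect_identical(pfb@ksPBoot, pfb2@ksPBoot)

  # degenerate: identical rescaled times do not crash, fit is rejected
  pfd <- suppressWarnings(fitPoissonCDF(mkUnbiasedEnsemble(rep(5, 10))))
  expect_lt(ksPValue(pfd), 0.01)

  expect_error(fitPoissonCDF(mkUnbiasedEnsemble(c(1, 2))), ">= 3")
})

test_that("trajectory bootstrap is deterministic and collapses for identical runs", {
  ens <- sampleTransitionTimes(linearRamp(0.015), 0.8, 1e-4, n = 60,
                               tMax = 1000, seed = 9)
  b1 <- bootstrapCI(ens, function(e) fitEATR(e, k0 = 1e-4), nBoot = 100,
                    seed = 42)
  b2 <- bootstrapCI(ens, function(e) fitEATR(e, k0 = 1e-4), nBoot = 100,
                    seed = 42)
  expect_identical(b1$gammaCI, b2$gammaCI)
  expect_identical(b1$k0CI, b2$k0CI)
  expect_error(bootstrapCI(ens, identity, nBoot = 50), ">= 100")

  # an ensemble of identical trajectories has a zero-width CI
  tr <- trajectories(ens)[[1]]
  same <- trajectoryEnsemble(rep(list(tr), 12), beta = 1)
  bs <- bootstrapCI(same, function(e) fitEATR(e, k0 = 1e-4), nBoot = 100,
                    seed = 3)
  expect_equal(diff(bs$gammaCI), 0)
  expect_equal(diff(bs$k0CI), 0)
})

test_that("per-trajectory and ensemble-mean fits agree on shared-schedule data", {
  ens <- sampleTransitionTimes(linearRamp(0.015), 0.8, 1e-4, n = 150,
                               tMax = 1000, seed = 51)
  gPT <- gammaHat(fitEATR(ens, k0 = 1e-4))
  gEM <- gammaHat(fitEATR(ens, k0 = 1e-4, averaging = "ensemble_mean"))
  expect_equal(gPT, 0.8, tolerance = 0.08)
  expect_equal(gEM, gPT, tolerance = 0.15)
})
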