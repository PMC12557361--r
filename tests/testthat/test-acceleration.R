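test_that("acceleration profiles match closed forms for flat and constant bias", {
  tr0 <- biasTrajectory(seq(0, 10, length.out = 101), rep(0, 101))
  p0 <- accelProfile(tr0, beta = 1)
  expect_equal(alphaValues(p0), rep(1, 101))
  expect_equal(tauAccel(p0)[101], 10)

  trc <- mkConstBiasTraj(log(2), 10)           # beta * v = ln 2
  pc <- accelProfile(trc, beta = 1)
  expect_equal(alphaValues(pc), rep(2, 101))
  expect_equal(tauAccel(pc)[101], 20)
  expect_equal(vMax(pc), rep(log(2), 101))

  expect_error(accelProfile(tr0, beta = -1), "parameter error")
})

test_that("trapezoid quadrature agrees with independent oracles", {
  # step bias: V = 0 on [0,5), beta*V = 1 on [5,10] -> tau_accel(10) = 5 + 5e
  n <- 10001
  tt <- seq(0, 10, length.out = n)
  v <- ifelse(tt < 5, 0, 1)
  tr <- biasTrajectory(tt, v)
  tau <- tauAccel(accelProfile(tr, beta = 1))[n]
  expect_equal(tau, 5 + 5 * exp(1), tolerance = 1e-3)

  # smooth bias against adaptive quadrature
  v2 <- 1 - cos(tt)
  tr2 <- biasTrajectory(tt, v2)
  tau2 <- tauAccel(accelProfile(tr2, beta = 1))[n]
  oracle <- integrate(function(x) exp(1 - cos(x)), 0, 10,
                      rel.tol = 1e-12)$value
  expect_equal(tau2, oracle, tolerance = 1e-6)

  # brute-force Riemann (midpoint) oracle on a much finer grid
  mid <- seq(0, 10, length.out = 100001)
  mid <- (mid[-1] + mid[-length(mid)]) / 2
  riemann <- sum(exp(1 - cos(mid))) * 10 / length(mid)
  expect_equal(tau2 / 10, riemann / 10, tolerance = 1e-6)
})

test_that("log-space accumulation survives beta*V far above overflow", {
  n <- 2001
  tt <- seq(0, 10, length.out = n)
  tr <- biasTrajectory(tt, 100 * tt)          # beta*V reaches 1000
  p <- accelProfile(tr, beta = 1)
  expect_true(all(is.finite(p@logTauAccel[-1])))
  # analytic: int exp(100 t) = (e^{1000} - 1)/100; compare in log space
  expect_equal(p@logTauAccel[n], 1000 - log(100), tolerance = 1e-4)
})

test_that("tau_accel dominates t, is monotone, and shifts exactly under V + c", {
  set.seed(7)
  for (rep in 1:10) {
    tr <- mkPiecewiseTraj()
    p <- accelProfile(tr, beta = 1)
    expect_true(all(diff(tauAccel(p)) >= 0))
    # >= up to round-off through the log-space accumulation
    expect_true(all(tauAccel(p)[-1] >= timeGrid(tr)[-1] * (1 - 1e-12)))
    expect_true(all(diff(vMax(p)) >= 0))

    shifted <- suppressWarnings(biasTrajectory(timeGrid(tr),
                                               biasValues(tr) + 1.7))
    ps <- accelProfile(shifted, beta = 1)
    expect_equal(tauAccel(ps)[-1], exp(1.7) * tauAccel(p)[-1],
                 tolerance = 1e-12)
  }
})

test_that("ensemble moments match hand-computed values", {
  # unbiased pair: (t, alpha) = (10, 1), (20, 1)
  ens <- mkUnbiasedEnsemble(c(10, 20))
  s <- ensembleSummary(ens)
  expect_equal(meanTauAccel(s), 15)
  expect_equal(meanAlpha(s), 1)
  expect_equal(covTauAlpha(s), 0)
  expect_equal(tauMFPT(s), 15)

  # single run, constant beta*V = ln 3, t = 4
  tr <- mkConstBiasTraj(log(3), 5, transitionTime = 4)
  s1 <- ensembleSummary(trajectoryEnsemble(list(tr), beta = 1))
  expect_equal(tauMFPT(s1), 12, tolerance = 1e-12)
  expect_equal(covTauAlpha(s1), 0)

  # (t, alpha) = (2, 10), (4, 100): population covariance 45, tau_MFPT 210
  trA <- mkConstBiasTraj(log(10), 3, transitionTime = 2)
  trB <- mkConstBiasTraj(log(100), 5, transitionTime = 4)
  ens2 <- trajectoryEnsemble(list(trA, trB), beta = 1)
  s2 <- ensembleSummary(ens2)
  expect_equal(meanAlpha(s2), 55, tolerance = 1e-12)
  expect_equal(tauMFPT(s2), 210, tolerance = 1e-12)
  expect_equal(covTauAlpha(s2), 45, tolerance = 1e-12)
  # brute-force covariance formula as an independent check
  tv <- c(2, 4); av <- c(10, 100)
  expect_equal(covTauAlpha(s2), mean(tv * av) - mean(tv) * mean(av),
               tolerance = 1e-12)
  # sample normalization doubles the two-point population value
  expect_equal(covTauAlpha(ensembleSummary(ens2,
                                           covNormalization = "sample")),
               90, tolerance = 1e-12)
})

test_that("accelTable reports censored runs and writes CSV", {
  trA <- mkConstBiasTraj(log(10), 3, transitionTime = 2)
  trC <- mkConstBiasTraj(log(10), 3)          # censored
  ens <- trajectoryEnsemble(list(trA, trC), beta = 1)
  tab <- accelTable(ens)
  expect_equal(tab$censored, c(FALSE, TRUE))
  expect_equal(tab$t, c(2, 3))
  p <- file.path(tempdir(), "accel.csv")
  accelTable(ens, path = p)
  expect_true(file.exists(p))
})
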