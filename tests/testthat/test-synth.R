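test_that("schedules satisfy their defining shapes", {
  lr <- linearRamp(0.5)
  expect_equal(evaluateSchedule(lr, c(0, 2, 4)), c(0, 1, 2))
  cr <- cappedRamp(0.5, tFill = 2)
  expect_equal(evaluateSchedule(cr, c(0, 1, 2, 10)), c(0, 0.5, 1, 1))
  h <- hillSchedule(centers = c(0, 0), heights = c(1, 1),
                    widths = c(0.5, 0.5), times = c(1, 2))
  ms <- metadSchedule(h, evalAt = 0)
  expect_equal(evaluateSchedule(ms, c(0.5, 1, 2.5)), c(0, 1, 2))
  expect_error(linearRamp(-1), "non-negative")
})

test_that("sampled times transformed by their own hazard are Exponential(1)", {
  ens <- sampleTransitionTimes(linearRamp(0.02), 0.7, 1e-3, n = 2000,
                               tMax = 2000, seed = 11)
  idx <- which(!isCensored(ens))
  H <- vapply(idx, function(i) {
    tr <- trajectories(ens)[[i]]
    1e-3 * exp(eatr:::logTrapzExpAt(timeGrid(tr), 0.7 * biasValues(tr),
                                    transitionTime(tr)))
  }, numeric(1))
  expect_gt(ks.test(H, "pexp", 1)$p.value, 0.01)
})

test_that("gamma 0 and constant-bias limits reduce to exponential laws", {
  # gamma = 0: bias on record, hazard plain Exponential(k0)
  ens0 <- sampleTransitionTimes(linearRamp(0.02), 0, 1e-3, n = 500,
                                tMax = 5e4, seed = 12)
  expect_equal(nCensored(ens0), 0L)
  expect_gt(ks.test(transitionTimes(ens0), "pexp", 1e-3)$p.value, 0.05)
  # the recorded bias is nonetheless nonzero (an ineffective ramp)
  expect_gt(max(biasValues(trajectories(ens0)[[1]])), 0)

  # gamma = 1, constant beta*V = ln 2: times Exponential(2 k0)
  ensC <- sampleTransitionTimes(cappedRamp(log(2) / 1e-3, 1e-3), 1, 1e-3,
                                n = 800, tMax = 3e4, seed = 13,
                                gridN = 2001L)
  expect_gt(ks.test(transitionTimes(ensC)[!isCensored(ensC)], "pexp",
                    2e-3)$p.value, 0.05)
})

test_that("linear-ramp sampling matches the closed-form median", {
  g <- 0.6; c0 <- 0.02; k0 <- 1e-3
  ens <- sampleTransitionTimes(linearRamp(c0), g, k0, n = 4000,
                               tMax = 3000, seed = 14)
  # H(t) = k0 (e^{g c t} - 1)/(g c); median solves H = log 2
  med <- log(1 + g * c0 * log(2) / k0) / (g * c0)
  expect_equal(median(transitionTimes(ens)), med, tolerance = 0.03)
})

test_that("end-to-end recovery: the generator/fit pair is self-consistent", {
  gh <- vapply(1:5, function(i) {
    ens <- sampleTransitionTimes(linearRamp(0.015), 0.6, 1e-4, n = 100,
                                 tMax = 1000, seed = 400 + i)
    gammaHat(fitEATR(ens, k0 = 1e-4))
  }, numeric(1))
  expect_lt(abs(mean(gh) - 0.6), 0.05)
})

test_that("Langevin engine reproduces equilibrium fluctuations", {
  # no barrier, no bias: y is harmonic with U = y^2/2, so var(y) = kB T
  set.seed(2)
  r <- eatr:::.langevinRunCpp(0, 90, 0, 0.2, Inf, 1000L, 0.005, 1, 1e6,
                              2e4, 10L, -1, 0)
  expect_equal(var(r$cv), 1, tolerance = 0.03)
})

test_that("zero hills leave the dynamics unbiased and consistent with k0Ref", {
  cfg <- toySystemConfig(barrierHeight = 3, hillHeight = 0, nRuns = 30L,
                         tMax = 500, seed = 9L)
  res <- langevinMetad(cfg)
  expect_equal(res$k0Method, "brute_force")
  s <- ensembleSummary(res$ensemble)
  expect_true(all(abs(perRunTable(s)$alpha - 1) < 1e-12))
  tt <- transitionTimes(res$ensemble)
  se <- sd(tt) / sqrt(length(tt))
  seRef <- 1 / res$k0Ref / sqrt(50)           # reference used 50 events
  expect_lt(abs(mean(tt) - 1 / res$k0Ref), 2 * sqrt(se^2 + seRef^2))

  # high barriers switch to the Kramers approximation, and the record says so
  cfg8 <- toySystemConfig(barrierHeight = 8, hillHeight = 0, nRuns = 1L,
                          tMax = 1, seed = 1L)
  res8 <- langevinMetad(cfg8)
  expect_equal(res8$k0Method, "kramers")
  expect_equal(res8$k0Ref, kramersRate(8))
})

test_that("orthogonal bias inflates tau_accel without helping the transition", {
  k0 <- kramersRate(8)
  cfg <- toySystemConfig(theta = 90, nRuns = 12L, tMax = 400, seed = 6L)
  res <- langevinMetad(cfg, estimateK0 = FALSE)
  fit <- fitEATR(res$ensemble, k0 = k0, averaging = "ensemble_mean")
  expect_lte(gammaHat(fit), 0.1)
  s <- ensembleSummary(res$ensemble)
  expect_gt(meanAlpha(s), 1)                   # bias was applied...
  # ...but the observed times are consistent with the unbiased rate
  cfg0 <- toySystemConfig(theta = 90, hillHeight = 0, nRuns = 12L,
                          tMax = 400, seed = 6L)
  res0 <- langevinMetad(cfg0, estimateK0 = FALSE)
  t1 <- transitionTimes(res$ensemble)
  t0 <- transitionTimes(res0$ensemble)
  expect_gt(suppressWarnings(
    ks.test(t1[!is.na(t1)], t0[!is.na(t0)])$p.value), 0.05)
})

test_that("integrator blow-up raises the step-size error", {
  cfg <- toySystemConfig(barrierHeight = 50, dt = 1, nRuns = 1L, tMax = 50,
                         commitThreshold = 1e4, seed = 1L)
  expect_error(langevinMetad(cfg, estimateK0 = FALSE), "step-size")
})

test_that("well-tempering shrinks hill heights as bias accumulates", {
  cfg <- toySystemConfig(theta = 0, biasFactor = 5, nRuns = 1L, tMax = 100,
                         seed = 3L, pace = 200L)
  res <- langevinMetad(cfg, estimateK0 = FALSE)
  h <- res$hills[[1]]
  expect_gt(length(h), 5L)
  expect_lt(min(h@heights), cfg@hillHeight)
  expect_true(all(h@heights <= cfg@hillHeight + 1e-12))
})

test_that("pace scan needs at least two paces", {
  cfg <- toySystemConfig(seed = 1L)
  expect_error(paceScan(cfg, paces = 500L), "at least two")
})
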