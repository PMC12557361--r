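# Fixtures built in code: small ensembles with known structure.

# Unbiased ensemble from explicit transition times (V identically zero).
mkUnbiasedEnsemble <- function(times, beta = 1) {
  trajs <- lapply(seq_along(times), function(i)
    biasTrajectory(c(0, times[i] * 1.01), c(0, 0),
                   transitionTime = times[i], label = sprintf("r%03d", i)))
  trajectoryEnsemble(trajs, beta = beta)
}

# One run with constant bias v (in energy units) on [0, tEnd]; the nonzero
# bias at t = 0 triggers the metadynamics-style warning by design.
mkConstBiasTraj <- function(v, tEnd, transitionTime = numeric(),
                            label = "const", n = 101) {
  suppressWarnings(biasTrajectory(seq(0, tEnd, length.out = n),
                                  rep(v, n), transitionTime = transitionTime,
                                  label = label))
}

# Random piecewise-constant bias profile on [0, tEnd] (V(0) = 0, V >= 0).
mkPiecewiseTraj <- function(tEnd = 50, nSeg = 6, vMax = 8, n = 201,
                            label = "pw") {
  tt <- seq(0, tEnd, length.out = n)
  edges <- sort(runif(nSeg - 1, 0, tEnd))
  lev <- c(0, runif(nSeg - 1, 0, vMax))
  v <- lev[findInterval(tt, c(0, edges))]
  suppressWarnings(biasTrajectory(tt, v, label = label))
}

writeLinesTo <- function(lines, dir = tempdir(), name = "fixture.dat") {
  p <- file.path(dir, name)
  writeLines(lines, p)
  p
}
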