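test_that("COLVAR parsing keeps named fields and validates structure", {
  p <- writeLinesTo(c("#! FIELDS time metad.bias",
                      "0 0", "1 0.5", "2 1.0"), name = "basic.colvar")
  tr <- readColvar(p)
  expect_s4_class(tr, "BiasTrajectory")
  expect_equal(timeGrid(tr), c(0, 1, 2))
  expect_equal(biasValues(tr), c(0, 0.5, 1.0))
  expect_true(isCensored(tr))

  expect_error(readColvar(writeLinesTo(c("0 0", "1 1"), name = "nohdr.dat")),
               "FIELDS")
  expect_error(readColvar(p, biasField = "absent"), "field error")
  expect_error(readColvar(writeLinesTo(c("#! FIELDS time metad.bias", "0 0"),
                                       name = "short.dat")),
               "fewer than 2")
})

test_that("restart overlaps resolve by keeping the last occurrence", {
  p <- writeLinesTo(c("#! FIELDS time metad.bias",
                      "0 0", "1 0.5", "1 0.7", "2 1.0"),
                    name = "restart.colvar")
  tr <- readColvar(p)
  expect_length(timeGrid(tr), 3L)
  expect_equal(biasValues(tr), c(0, 0.7, 1.0))

  # rewound restart: the replayed segment supersedes the original
  p2 <- writeLinesTo(c("#! FIELDS time metad.bias",
                       "0 0", "1 0.1", "2 0.2", "3 0.3",
                       "1.5 0.15", "2.5 0.25", "3.5 0.35"),
                     name = "rewind.colvar")
  tr2 <- readColvar(p2)
  expect_true(all(diff(timeGrid(tr2)) > 0))
  expect_equal(timeGrid(tr2), c(0, 1, 1.5, 2.5, 3.5))
})

test_that("HILLS parsing handles the dialect, empty bodies and bad sigma", {
  p <- writeLinesTo(c("#! FIELDS time cv sigma_cv height biasf",
                      "10 0.1 0.1 1.2 10", "20 0.2 0.1 1.2 10"),
                    name = "two.hills")
  h <- readHills(p)
  expect_length(h, 2L)
  expect_equal(as.data.frame(h)$height, c(1.2, 1.2))

  empty <- readHills(writeLinesTo("#! FIELDS time cv sigma_cv height",
                                  name = "empty.hills"))
  expect_length(empty, 0L)

  expect_error(readHills(writeLinesTo(
    c("#! FIELDS time cv sigma_cv height", "10 0.1 0 1.2"),
    name = "badsigma.hills")), "sigma")
})

test_that("trajectory and hill round-trips are exact", {
  set.seed(1)
  tr <- biasTrajectory(sort(runif(50, 0, 100)),
                       c(0, cumsum(runif(49, 0, 0.3))),
                       cv = rnorm(50), label = "rt")
  p <- file.path(tempdir(), "rt.colvar")
  writeColvar(tr, p)
  back <- readColvar(p, cvField = "cv")
  expect_identical(timeGrid(back), timeGrid(tr))
  expect_identical(biasValues(back), biasValues(tr))
  expect_identical(cvValues(back), cvValues(tr))

  h <- hillSchedule(centers = rnorm(9), heights = runif(9),
                    widths = runif(9, 0.05, 0.3), times = sort(runif(9)))
  ph <- file.path(tempdir(), "rt.hills")
  writeHills(h, ph)
  hb <- readHills(ph)
  expect_identical(hb@centers, h@centers)
  expect_identical(hb@heights, h@heights)
  expect_identical(hb@widths, h@widths)
  expect_identical(hb@times, h@times)
})

test_that("threshold assembly counts crossings and interpolates times", {
  mkcv <- function(slope) {
    tt <- 0:10
    suppressWarnings(biasTrajectory(tt, rep(0, 11), cv = slope * tt))
  }
  trajs <- c(lapply(c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7), mkcv),
             lapply(c(0.05, 0.08), mkcv))  # these never reach 1.0
  ens <- assembleEnsemble(trajs, beta = 1, threshold = 1.0)
  expect_equal(nTransitions(ens), 6L)
  expect_equal(nCensored(ens), 2L)
  # first-passage interpolation: cv = 0.4 t crosses 1.0 at t = 2.5
  expect_equal(transitionTimes(ens)[3], 2.5)

  # explicit times for all: no censoring
  ens2 <- assembleEnsemble(trajs[1:3], beta = 1,
                           transitionTimes = c(1, 2, 3))
  expect_equal(nCensored(ens2), 0L)

  # none cross: all censored, moment summary refuses, fixed-k0 fit works
  ens3 <- assembleEnsemble(trajs[7:8], beta = 1, threshold = 1.0)
  expect_equal(nCensored(ens3), 2L)
  expect_error(ensembleSummary(ens3), "estimation error")
  expect_error(fitEATR(ens3), "k0 is unidentifiable")
  expect_s4_class(fitEATR(ens3, k0 = 0.01), "RateFit")
})

test_that("raising the CV threshold never shortens transition times", {
  set.seed(42)
  for (rep in 1:5) {
    tt <- seq(0, 20, length.out = 201)
    cv <- cumsum(abs(rnorm(201, 0.02, 0.05)))  # monotone escape CV
    tr <- suppressWarnings(biasTrajectory(tt, rep(0, 201), cv = cv))
    thr <- sort(runif(5, min(cv), max(cv)))
    times <- vapply(thr, function(h)
      transitionTimes(assembleEnsemble(list(tr), beta = 1,
                                       threshold = h))[1], numeric(1))
    expect_true(all(diff(times) >= 0))
  }
})

test_that("manifests round-trip an ensemble with its transition rule", {
  d <- file.path(tempdir(), "man-test")
  dir.create(d, showWarnings = FALSE)
  tt <- seq(0, 10, 0.5)
  for (i in 1:3) {
    tr <- suppressWarnings(biasTrajectory(tt, 0.1 * tt, cv = 0.1 * i * tt))
    writeColvar(tr, file.path(d, sprintf("run%d.colvar", i)))
  }
  yaml::write_yaml(list(beta = 2.0, iteration_label = "it1",
                        time_field = "time", bias_field = "metad.bias",
                        cv_field = "cv",
                        transition = list(type = "threshold",
                                          threshold = 1.5,
                                          direction = "above"),
                        trajectories = sprintf("run%d.colvar", 1:3)),
                   file.path(d, "manifest.yaml"))
  ens <- readEnsembleManifest(file.path(d, "manifest.yaml"))
  expect_equal(length(ens), 3L)
  expect_equal(thermalBeta(ens), 2.0)
  expect_equal(iterationLabel(ens), "it1")
  # cv = 0.1 t never reaches 1.5 within [0,10]; 0.2 t crosses at 7.5;
  # 0.3 t crosses at 5
  expect_equal(nCensored(ens), 1L)
  expect_equal(unname(transitionTimes(ens)[2:3]), c(7.5, 5))

  # merging ensembles with clashing units is a unit error
  ens2 <- trajectoryEnsemble(trajectories(ens), beta = 2.0,
                             timeUnit = "ns")
  expect_error(mergeEnsembles(list(ens, ens2)), "unit error")
})

test_that("trajectory validity enforces the grid invariants", {
  expect_error(biasTrajectory(c(0, 1, 1), c(0, 0, 0)), "strictly increasing")
  expect_error(biasTrajectory(c(0, 1), c(0, NaN)), "finite")
  expect_error(biasTrajectory(c(0, 1), c(0, 0), transitionTime = 2),
               "transitionTime")
  expect_warning(biasTrajectory(c(0, 1), c(0.5, 0.5)), "bias\\(0\\)")
})
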