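test_that("squared displacements follow the gap and last-point rules", {
  # 3-4-5 displacement with a dummy terminal point so the pair is kept
  tr <- data.frame(frame = 0:2, x = c(0, 0.3, 0.3), y = c(0, 0.4, 0.4))
  sq <- squaredDisplacements(makeTrackSet(list(tr)))
  expect_equal(sq$sqd[1], 0.25)
  # the pair ending at the last localization is excluded
  expect_equal(nrow(sq), 1L)

  # no displacement bridges a gap
  gappy <- data.frame(frame = c(0:4, 7:10), x = seq(0, 0.8, by = 0.1),
                      y = 0)
  sq2 <- squaredDisplacements(makeTrackSet(list(gappy)))
  expect_equal(nrow(sq2), 6L)  # 4 pre-gap pairs + 3 post-gap, minus last

  # analytic oracle: mean SQD = 4 D dt
  ts <- simulateTracks(simConfig(D = 0.05, fractions = 1, locErrorSd = 0,
                                 bleachProb = 0.05, nTracks = 3000,
                                 seed = 12))
  sq3 <- squaredDisplacements(ts)$sqd
  expect_lt(abs(mean(sq3) - 0.0048), 3 * sd(sq3) / sqrt(length(sq3)))

  expect_error(squaredDisplacements(ts, lagFrames = 0), "lagFrames")
})

test_that("ensemble MSD matches closed forms for still, ballistic and
           Brownian motion", {
  still <- makeTrackSet(list(stillTrack(10), stillTrack(8)))
  expect_equal(ensembleMSD(still)@msd, rep(0, 4))

  # deterministic drift at v = 1 um/s: MSD(k dt) = (k dt)^2
  dr <- makeTrackSet(list(driftTrack(20)))
  curve <- ensembleMSD(dr)
  expect_equal(curve@msd, ((1:4) * 0.024)^2, tolerance = 1e-12)

  # Brownian with localization error: MSD = 4 D t + 4 sigma^2 within 5%
  D <- 0.142; s <- 0.02
  ts <- simulateTracks(simConfig(D = D, fractions = 1, locErrorSd = s,
                                 bleachProb = 0.05, nTracks = 5000,
                                 seed = 13))
  curve2 <- ensembleMSD(filterTracks(ts))
  expected <- 4 * D * curve2@lags + 4 * s^2
  expect_true(all(abs(curve2@msd - expected) / expected < 0.05))
})

test_that("linear MSD fit inverts exact lines and recovers simulated
           diffusion coefficients", {
  lags <- (1:4) * 0.024
  exact <- new("MsdCurve", lags = lags, msd = 4 * 0.1 * lags + 0.002,
               nPairs = rep(100L, 4), frameInterval = 0.024)
  fit <- fitMsdLinear(exact)
  expect_equal(fit@D, 0.1, tolerance = 1e-10)
  expect_equal(fit@intercept, 0.002, tolerance = 1e-10)

  one <- new("MsdCurve", lags = 0.024, msd = 0.01, nPairs = 10L,
             frameInterval = 0.024)
  expect_error(fitMsdLinear(one), "two lags")
})

test_that("single-component SQD fit equals the closed-form exponential
           CDF fit", {
  dt <- 0.024
  sq <- simulateSquaredDisplacements(1, 0.05, dt, 500, seed = 14)
  fit <- fitSqdMixtureGlobal(list(x = as.numeric(sq)), nComponents = 1,
                             frameInterval = dt)
  # independent oracle: 1-D golden-section over the same least-squares
  # criterion on the sorted sample
  xs <- sort(as.numeric(sq))
  Fe <- seq_along(xs) / length(xs)
  oracle <- optimize(function(m) sum((1 - exp(-xs / m) - Fe)^2),
                     interval = c(1e-6, 1), tol = 1e-12)$minimum / (4 * dt)
  expect_equal(diffusionCoefficients(fit), oracle, tolerance = 1e-3)
  expect_equal(unname(fractions(fit)[1, 1]), 1)
})

test_that("global fit gives identical conditions identical fractions
           and respects the simplex", {
  sq <- simulateSquaredDisplacements(c(0.6, 0.4), c(0.01, 0.2), 0.024,
                                     8000, seed = 15)
  fit <- fitSqdMixtureGlobal(list(a = as.numeric(sq),
                                  b = as.numeric(sq)),
                             nComponents = 2, frameInterval = 0.024)
  expect_equal(fractions(fit)["a", ], fractions(fit)["b", ],
               tolerance = 1e-6)
  expect_equal(unname(rowSums(fractions(fit))), c(1, 1), tolerance = 1e-9)
  expect_true(all(fractions(fit) >= 0 & fractions(fit) <= 1))
  expect_true(all(diff(diffusionCoefficients(fit)) > 0))

  expect_error(fitSqdMixtureGlobal(list(x = 1:10), 2, 0.024),
               ">= 200")
})

test_that("recovery error of the mixture fit shrinks with sample size", {
  dt <- 0.024
  err <- function(n, seed) {
    sq <- simulateSquaredDisplacements(1, 0.05, dt, n, seed = seed)
    abs(diffusionCoefficients(
      fitSqdMixtureGlobal(list(x = as.numeric(sq)), 1, dt)) - 0.05)
  }
  seeds <- 1:10
  small <- vapply(seeds, function(s) err(1000, s), numeric(1))
  large <- vapply(seeds, function(s) err(100000, 100 + s), numeric(1))
  expect_lt(mean(large), mean(small))
})

test_that("track classification recovers well-separated ground truth", {
  cfg <- simConfig(D = c(0.005, 0.5), fractions = c(0.5, 0.5),
                   locErrorSd = 0, bleachProb = 0.05, nTracks = 400,
                   seed = 16)
  ts <- filterTracks(simulateTracks(cfg))
  mix <- new("DiffusionMixture", D = c(0.005, 0.5),
             fractions = matrix(0.5, 1, 2,
                                dimnames = list("simulated", NULL)),
             seD = rep(NA_real_, 2),
             seFractions = matrix(NA_real_, 1, 2),
             nSteps = c(simulated = 1000), frameInterval = 0.024)
  lab <- classifyTracks(ts, mix)
  d <- tracks(lab)
  perTrack <- !duplicated(d$track_id)
  truth <- ifelse(d$state[perTrack] == 1, "confined", "fast")
  expect_gt(mean(d$label[perTrack] == truth), 0.9)

  # stationary steps against well-separated components: confined
  still <- classifyTracks(makeTrackSet(list(stillTrack(10))), mix)
  expect_true(all(tracks(still)$label == "confined"))

  # an empty set passes through
  empty <- trackSet(data.frame(track_id = integer(), frame = integer(),
                               x = numeric(), y = numeric()), 0.024)
  expect_equal(nrow(tracks(classifyTracks(empty, mix))), 0L)
})
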