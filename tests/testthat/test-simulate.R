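test_that("simulator honours its degenerate and analytic limits", {
  # zero diffusion, zero localization error: frozen molecules
  ts <- simulateTracks(simConfig(D = 0, fractions = 1, locErrorSd = 0,
                                 nTracks = 20, seed = 1))
  sp <- split(tracks(ts), tracks(ts)$track_id)
  expect_true(all(vapply(sp, function(d)
    max(abs(d$x - d$x[1])) + max(abs(d$y - d$y[1])) == 0, logical(1))))

  # mean squared one-frame step = 4 D dt within 3 SE (D = 0.05, 24 ms)
  ts <- simulateTracks(simConfig(D = 0.05, fractions = 1, locErrorSd = 0,
                                 bleachProb = 0.05, nTracks = 5000,
                                 seed = 2))
  sq <- squaredDisplacements(ts)$sqd
  se <- sd(sq) / sqrt(length(sq))
  expect_lt(abs(mean(sq) - 4 * 0.05 * 0.024), 3 * se)

  # equal fractions split tracks evenly (binomial 99% CI)
  ts <- simulateTracks(simConfig(D = c(0.01, 0.1),
                                 fractions = c(0.5, 0.5),
                                 nTracks = 2000, seed = 3))
  st <- tapply(tracks(ts)$state, tracks(ts)$track_id, function(s) s[1])
  p0 <- mean(st == 1)
  expect_lt(abs(p0 - 0.5), 2.58 * sqrt(0.25 / 2000))
})

test_that("simulator is seed-deterministic and respects geometry and
           bleaching statistics", {
  cfg <- simConfig(D = 0.05, fractions = 1, nTracks = 50, seed = 42)
  expect_identical(tracks(simulateTracks(cfg)), tracks(simulateTracks(cfg)))

  g <- cellGeometry("rod", length = 3, width = 1)
  ts <- simulateTracks(simConfig(D = 0.3, fractions = 1, locErrorSd = 0,
                                 bleachProb = 0.02, nTracks = 100,
                                 geometry = g, seed = 5))
  expect_true(all(insideGeometry(g, tracks(ts)$x, tracks(ts)$y,
                                 tol = 1e-9)))

  # geometric track lengths: mean 1/p within 3 SE
  p <- 0.05
  ts <- simulateTracks(simConfig(D = 0.05, fractions = 1, bleachProb = p,
                                 nTracks = 2000, seed = 6))
  len <- tapply(tracks(ts)$frame, tracks(ts)$track_id, length)
  se <- sd(len) / sqrt(length(len))
  expect_lt(abs(mean(len) - 1 / p), 3 * se)
})

test_that("simulator rejects invalid configurations", {
  expect_error(simConfig(D = numeric(0)), "empty")
  expect_error(simConfig(D = -0.1, fractions = 1), "non-negative|>= 0")
  expect_error(simConfig(D = c(0.1, 0.2), fractions = c(0.6, 0.6)),
               "sum to 1")
})

test_that("dwell-duration generator matches its analytic mixture mean
           and discretization contract", {
  # pure exponential, no discretization: mean tau within 3 SE
  d <- simulateDwellDurations(1, 0.1, 1, 1e5, frameInterval = 0, seed = 7)
  expect_lt(abs(mean(d) - 0.1), 3 * sd(d) / sqrt(length(d)))

  # continuous mixture mean for the C. glutamicum wild-type parameters
  d <- simulateDwellDurations(0.347, 0.19, 0.76, 1e5, frameInterval = 0,
                              seed = 8)
  mu <- 0.347 * 0.19 + 0.653 * 0.76
  expect_lt(abs(mean(d) - mu), 3 * sd(d) / sqrt(length(d)))

  # every discretized duration is a whole number of frames
  d <- simulateDwellDurations(0.3, 0.2, 0.8, 5000, frameInterval = 0.024,
                              seed = 9)
  expect_true(all(abs(d / 0.024 - round(d / 0.024)) < 1e-9))
  expect_true(all(d > 0))
  expect_error(simulateDwellDurations(0.5, -1, 1, 10, 0.024), "positive")
  expect_error(simulateDwellDurations(0.5, 1, 1, 0, 0.024), "positive")
})

test_that("FRAP generator reproduces its noiseless identities", {
  # A = 1, no noise, no acquisition bleaching: normalized recovery is
  # exactly 1 - exp(-tau t) from the anchor
  raw <- simulateFrapSeries(A = 1, tau = 0.05, noiseSd = 0,
                            acqBleachRate = 0)
  cv <- normalizeFrap(raw)
  d <- cv@data[cv@data$t_fit >= 0, ]
  expect_equal(d$normalized, 1 - exp(-0.05 * d$t_fit), tolerance = 1e-12)

  # immobile limit: flat post-bleach signal at the bleach floor
  raw0 <- simulateFrapSeries(A = 0, tau = 0.05, noiseSd = 0)
  post <- raw0[raw0$time_s >= 0, ]
  focus <- computeCTCF(post$roi_integrated_density, post$roi_area,
                       post$background_mean)
  cell <- computeCTCF(post$cell_integrated_density, post$cell_area,
                      post$background_mean)
  expect_equal(focus / cell, rep(0.3 * 0.2, nrow(post)), tolerance = 1e-12)

  # whole-cell channel decays exactly exponentially under acquisition
  # bleaching
  k <- 0.01
  raw <- simulateFrapSeries(A = 0.8, tau = 0.05, noiseSd = 0,
                            acqBleachRate = k)
  cell <- computeCTCF(raw$cell_integrated_density, raw$cell_area,
                      raw$background_mean)
  expect_equal(cell, 1e5 * exp(-k * (raw$time_s - raw$time_s[1])),
               tolerance = 1e-10)
  expect_error(simulateFrapSeries(A = 1.5, tau = 0.1), "A must")
})
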