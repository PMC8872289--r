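test_that("dwell detection matches constructed tracks exactly", {
  # fully stationary track: one censored event spanning all frames
  ev <- detectDwellEvents(makeTrackSet(list(stillTrack(10))))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_frames, 10L)
  expect_true(ev$censored)
  expect_equal(ev$duration_s, 10 * 0.024)

  # straight line with 200 nm steps: every step breaks the radius
  line <- data.frame(frame = 0:9, x = 0.2 * (0:9), y = 0)
  expect_equal(nrow(detectDwellEvents(makeTrackSet(list(line)))), 0L)

  # 8 immobile frames then large jumps: one complete 8-frame event
  mixed <- data.frame(frame = 0:12,
                      x = c(rep(0, 8), cumsum(rep(1, 5))), y = 0)
  ev3 <- detectDwellEvents(makeTrackSet(list(mixed)))
  expect_equal(nrow(ev3), 1L)
  expect_equal(ev3$n_frames, 8L)
  expect_false(ev3$censored)

  expect_error(detectDwellEvents(makeTrackSet(list(stillTrack(5))),
                                 radius = 0), "radius")
})

test_that("dwell events never overlap and never lengthen as the radius
           shrinks", {
  set.seed(17)
  ts <- simulateTracks(simConfig(D = 0.02, fractions = 1,
                                 locErrorSd = 0.02, bleachProb = 0.02,
                                 nTracks = 40, seed = 17))
  ev <- detectDwellEvents(ts)
  for (d in split(ev, ev$track_id)) {
    d <- d[order(d$start_frame), ]
    if (nrow(d) > 1)
      expect_true(all(d$start_frame[-1] >
                      (d$start_frame + d$n_frames - 1)[-nrow(d)]))
  }
  longest <- vapply(c(0.2, 0.15, 0.097, 0.05), function(r) {
    e <- detectDwellEvents(ts, radius = r)
    if (nrow(e)) max(e$duration_s) else 0
  }, numeric(1))
  expect_true(all(diff(longest) <= 1e-12))
})

test_that("survival curve counts, stays monotone, and matches the
           exponential law", {
  s <- dwellSurvival(c(1, 2, 3), frameInterval = 1, minEvents = 1)
  expect_equal(s$surv[1:3], c(1, 2 / 3, 1 / 3))

  d <- simulateDwellDurations(0.4, 0.1, 0.5, 500, 0.024, seed = 18)
  s2 <- dwellSurvival(d, frameInterval = 0.024, minEvents = 1)
  expect_true(all(diff(s2$surv) <= 0))
  expect_equal(s2$surv[1], 1)

  # 1e5 exponential samples: after the one-frame discretization
  # correction the survival matches exp(-t/tau) within 0.01 sup-norm
  tau <- 0.5; dt <- 0.024
  d3 <- simulateDwellDurations(1, tau, 1, 1e5, dt, seed = 19)
  s3 <- dwellSurvival(d3, frameInterval = dt, minEvents = 1)
  cont <- exp(-(s3$time_s - dt) / tau)
  expect_lt(max(abs(s3$surv - cont)), 0.01)

  expect_error(dwellSurvival(numeric(0), 0.024), "no dwell events")
  expect_error(dwellSurvival(rep(1, 10), 1), "fewer than 50")
})

test_that("biexponential survival fit collapses gracefully on
           single-exponential data", {
  d <- simulateDwellDurations(1, 0.3, 1, 20000, 0.024, seed = 20)
  s <- dwellSurvival(d, frameInterval = 0.024)
  fit <- fitSurvivalBiexponential(s)
  # either both time constants agree or one component vanishes
  collapsed <- abs(log(fit@tau[2] / fit@tau[1])) < 0.25 ||
    min(fit@p) < 0.05
  expect_true(collapsed)
  # whichever way, the dominant time constant is right
  eff <- sum(fit@p * fit@tau)
  expect_lt(abs(eff - 0.3) / 0.3, 0.1)
})

test_that("survival fit round-trips its own parameters", {
  d <- simulateDwellDurations(0.35, 0.2, 0.8, 20000, 0.024, seed = 21)
  fit <- fitSurvivalBiexponential(dwellSurvival(d, frameInterval = 0.024))
  d2 <- simulateDwellDurations(fit@p[1], fit@tau[1], fit@tau[2], 20000,
                               0.024, seed = 22)
  fit2 <- fitSurvivalBiexponential(dwellSurvival(d2,
                                                 frameInterval = 0.024))
  expect_equal(fit2@tau, fit@tau, tolerance = 0.1)
  expect_equal(fit2@p, fit@p, tolerance = 0.05)
})

test_that("confinement heat map conserves counts and respects the
           imposed symmetry", {
  g <- cellGeometry("rod", length = 3, width = 1)
  set.seed(23)
  n <- 20000
  pts <- samplePointsInGeometry(g, n)
  tr <- data.frame(track_id = rep(seq_len(n / 2), each = 2),
                   frame = rep(0:1, n / 2), x = pts$x, y = pts$y,
                   label = "confined")
  ts <- trackSet(tr, 0.024, "uniform")
  hm <- confinementHeatmap(ts, g, bins = c(10, 10))
  expect_equal(sum(hm@counts), n)
  expect_equal(hm@nPoints, n)
  # short-axis mirror symmetry is exact by construction
  expect_equal(hm@counts, hm@counts[, ncol(hm@counts):1],
               tolerance = 1e-12)
  # away from the support edges (cell tip, side walls) the smoothed
  # density of uniform occupancy is flat within 10%
  core <- hm@density[2:6, 3:8]
  expect_lt(max(abs(core - mean(core))) / mean(core), 0.1)

  tr$label <- "fast"
  expect_warning(empty <- confinementHeatmap(trackSet(tr, 0.024, "u"), g),
                 "no localizations")
  expect_equal(empty@nPoints, 0L)
})
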