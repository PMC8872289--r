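test_that("CTCF is the background-corrected integrated density", {
  expect_equal(computeCTCF(1000, 100, 2), 800)
  expect_equal(computeCTCF(500, 50, 0), 500)
  expect_equal(computeCTCF(200, 100, 2), 0)
  expect_error(computeCTCF(1000, -1, 2), "area")
})

test_that("normalization cancels acquisition bleaching, hits its
           anchors, and is affine-invariant", {
  raw <- simulateFrapSeries(A = 0.7, tau = 0.04, noiseSd = 0,
                            acqBleachRate = 0.005)
  cv <- normalizeFrap(raw)
  # the focus/cell ratio is constant before the bleach
  pre <- cv@data$ratio[cv@data$phase == "pre"]
  expect_lt(diff(range(pre)), 1e-12)
  # anchors map exactly to 1 and 0
  expect_equal(mean(cv@data$normalized[cv@data$phase == "pre"]), 1,
               tolerance = 1e-12)
  expect_equal(cv@data$normalized[cv@data$t_fit == 0], 0,
               tolerance = 1e-12)
  # acquisition bleaching leaves the normalized curve unchanged
  for (k in c(0, 0.001, 0.01)) {
    rawk <- simulateFrapSeries(A = 0.7, tau = 0.04, noiseSd = 0,
                               acqBleachRate = k)
    expect_equal(normalizeFrap(rawk)@data$normalized,
                 cv@data$normalized, tolerance = 1e-9)
  }
  # a consistent gain on all intensities changes nothing
  gained <- raw
  gained$roi_integrated_density <- raw$roi_integrated_density * 3
  gained$cell_integrated_density <- raw$cell_integrated_density * 3
  gained$background_mean <- raw$background_mean * 3
  expect_equal(normalizeFrap(gained)@data$normalized,
               cv@data$normalized, tolerance = 1e-12)

  noPre <- raw[raw$time_s >= 0, ]
  expect_error(normalizeFrap(noPre), "pre-bleach")
  expect_error(normalizeFrap(raw[, -2]), "missing column")
})

test_that("recovery fit inverts noiseless curves and obeys the
           halftime identity", {
  raw <- simulateFrapSeries(A = 0.8, tau = 0.05, noiseSd = 0)
  fit <- fitFrapRecovery(normalizeFrap(raw))
  expect_equal(fit@A, 0.8, tolerance = 1e-8)
  expect_equal(fit@tau, 0.05, tolerance = 1e-8)
  expect_equal(fit@tHalf, log(2) / 0.05, tolerance = 1e-6)
  expect_equal(fit@immobile, 0.2, tolerance = 1e-8)
  expect_equal(fit@tHalf * fit@tau, log(2), tolerance = 1e-12)

  # identity case: tau = ln 2 gives a 1 s halftime
  tt <- seq(0, 10, by = 0.5)
  fit2 <- fitFrapRecovery(data.frame(t_fit = tt,
                                     normalized = 1 - exp(-log(2) * tt)))
  expect_equal(fit2@tHalf, 1, tolerance = 1e-8)
  expect_equal(fit2@tHalf * fit2@tau, log(2), tolerance = 1e-12)

  expect_error(fitFrapRecovery(data.frame(t_fit = 0:3,
                                          normalized = rep(0.1, 4))),
               "5 post-anchor")
})

test_that("halftime recovery stays accurate under measurement noise", {
  # validated envelope: large mobile fractions and halftimes of a few
  # frame intervals, with the series covering several halftimes plus
  # plateau (see the methods vignette for the information analysis
  # behind this envelope; shorter halftimes cannot be resolved at a
  # 20 s frame spacing)
  tt <- (0:59) * 20
  set.seed(24)
  for (cfg in list(c(A = 0.9, th = 60), c(A = 0.8, th = 100),
                   c(A = 0.9, th = 100))) {
    tau <- log(2) / cfg[["th"]]
    relErr <- replicate(200, {
      y <- cfg[["A"]] * (1 - exp(-tau * tt)) +
        rnorm(length(tt), sd = 0.05)
      fit <- fitFrapRecovery(data.frame(t_fit = tt, normalized = y))
      abs(fit@tHalf - cfg[["th"]]) / cfg[["th"]]
    })
    expect_lte(median(relErr), 0.05)
  }
  # mobile fraction is recovered without systematic bias (30 frames)
  set.seed(25)
  t30 <- (0:29) * 20
  tau <- log(2) / 60
  Ahat <- replicate(200, {
    y <- 0.8 * (1 - exp(-tau * t30)) + rnorm(length(t30), sd = 0.05)
    fitFrapRecovery(data.frame(t_fit = t30, normalized = y))@A
  })
  expect_lt(abs(mean(Ahat) - 0.8) / 0.8, 0.02)
})

test_that("group comparison follows the assumption-driven decision
           path", {
  set.seed(26)
  # identical samples: nothing significant
  v <- rep(c(1, 2, 3, 4), 3)
  g <- rep(c("wt", "a", "b"), each = 4)
  res <- compareGroups(v, g, control = "wt")
  expect_true(all(res$comparisons$p_value > 0.05))

  # clean normal shift: parametric path, high power (one-sided "less")
  rej <- replicate(200, {
    vals <- c(rnorm(12, 20, 2), rnorm(12, 15, 2))
    grp <- rep(c("control", "treated"), each = 12)
    r <- compareGroups(vals, grp, control = "control")
    r$comparisons$p_value < 0.05
  })
  expect_gte(mean(rej), 0.8)

  # non-normal data fall back to the rank-based path
  vals <- c(rexp(12)^3, rexp(12)^3 + 5)
  grp <- rep(c("control", "treated"), each = 12)
  expect_identical(compareGroups(vals, grp)$path, "rank")

  expect_error(compareGroups(c(1, 2, 3), rep("a", 3)), "two groups")
  expect_error(compareGroups(c(1, 2, 1, 2), c("a", "a", "b", "b")),
               "at least 3")
})
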