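#' Construct a TrackSet
#'
#' @param tracks `data.frame` with columns `track_id`, `frame`, `x`, `y`
#'   (um); optional `state` (ground-truth component) and `label`.
#' @param frameInterval frame interval, s.
#' @param condition condition label.
#' @return a [TrackSet-class].
#' @export
trackSet <- function(tracks, frameInterval, condition = "condition") {
  tracks <- as.data.frame(tracks)
  if (nrow(tracks))
    tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  new("TrackSet", tracks = tracks, frameInterval = as.numeric(frameInterval),
      condition = as.character(condition))
}

#' Construct a simulation configuration
#'
#' @param D per-component diffusion coefficients, um^2/s.
#' @param fractions per-component population fractions (sum to 1).
#'   Defaults to a single component.
#' @param frameInterval frame interval, s. The acquisition settings
#'   modelled here use 0.024 s (20 ms exposure) or 0.009 s (5 ms
#'   exposure), both including camera transfer time.
#' @param locErrorSd localization error sd per axis, um (default 0.02,
#'   typical for TMR-labelled HaloTag SMLM).
#' @param bleachProb per-frame termination probability; track lengths
#'   are geometric with mean `1/bleachProb` (default 0.05, mean 20).
#' @param nTracks number of tracks.
#' @param geometry optional bounding [CellGeometry-class].
#' @param switchProb per-frame probability of re-drawing the diffusive
#'   state; 0 keeps the state fixed per molecule.
#' @param seed integer RNG seed.
#' @return a [SimConfig-class].
#' @examples
#' simConfig(D = c(0.005, 0.05, 0.5), fractions = c(0.76, 0.23, 0.01),
#'           frameInterval = 0.024, nTracks = 100)
#' @export
simConfig <- function(D, fractions = rep(1 / length(D), length(D)),
                      frameInterval = 0.024, locErrorSd = 0.02,
                      bleachProb = 0.05, nTracks = 1000L, geometry = NULL,
                      switchProb = 0, seed = 1L) {
  if (length(D) == 0L) stop("components list must not be empty")
  if (any(D < 0)) stop("diffusion coefficients must be >= 0")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1")
  new("SimConfig", D = as.numeric(D), fractions = as.numeric(fractions),
      frameInterval = as.numeric(frameInterval),
      locErrorSd = as.numeric(locErrorSd),
      bleachProb = as.numeric(bleachProb), nTracks = as.integer(nTracks),
      geometry = geometry, switchProb = as.numeric(switchProb),
      seed = as.integer(seed))
}

#' Simulate multi-state Brownian tracks
#'
#' Each track draws one diffusive component with probability equal to
#' its fraction and keeps it for its whole lifetime (unless
#' `switchProb > 0`). Per-frame displacements are isotropic Gaussian
#' with variance `2 D dt` per axis; a bounding geometry reflects steps
#' specularly at the cell outline; localization error is added as
#' independent Gaussian noise per localization after boundary handling,
#' so the underlying positions always lie inside the cell. Tracks
#' terminate with probability `bleachProb` per frame.
#'
#' @param config a [SimConfig-class].
#' @param maxFrames hard cap on track length (caps the geometric
#'   length distribution; also the track length used when
#'   `bleachProb = 0`).
#' @param condition condition label for the output.
#' @return a [TrackSet-class] whose table carries the ground-truth
#'   component index in column `state`.
#' @examples
#' ts <- simulateTracks(simConfig(D = 0.05, nTracks = 10, seed = 7))
#' nTracks(ts)
#' @export
simulateTracks <- function(config, maxFrames = 1000L,
                           condition = "simulated") {
  validObject(config)
  set.seed(config@seed)
  n <- config@nTracks
  dt <- config@frameInterval
  k <- length(config@D)

  len <- if (config@bleachProb > 0)
    pmin(stats::rgeom(n, config@bleachProb) + 1L, as.integer(maxFrames))
  else rep(as.integer(maxFrames), n)
  state0 <- sample.int(k, n, replace = TRUE, prob = config@fractions)

  id <- rep.int(seq_len(n), len)
  frame <- sequence(len) - 1L
  total <- length(id)

  state <- rep.int(state0, len)
  if (config@switchProb > 0 && k > 1) {
    # re-draw the state at flagged frames, carrying it forward
    for (i in which(len > 1L)) {
      idx <- which(id == i)
      s <- state0[i]
      for (j in idx[-1]) {
        if (stats::runif(1) < config@switchProb)
          s <- sample.int(k, 1, prob = config@fractions)
        state[j] <- s
      }
    }
  }

  stepSd <- sqrt(2 * config@D * dt)[state]
  first <- !duplicated(id)
  dx <- stats::rnorm(total) * stepSd
  dy <- stats::rnorm(total) * stepSd
  dx[first] <- 0
  dy[first] <- 0

  if (is.null(config@geometry)) {
    x <- stats::ave(dx, id, FUN = cumsum)
    y <- stats::ave(dy, id, FUN = cumsum)
  } else {
    start <- samplePointsInGeometry(config@geometry, n)
    x <- numeric(total)
    y <- numeric(total)
    x[first] <- start$x
    y[first] <- start$y
    # advance all live tracks one frame at a time, reflecting at walls
    maxLen <- max(len)
    offs <- c(0L, cumsum(len))
    for (f in seq_len(maxLen - 1L)) {
      live <- which(len > f)
      if (!length(live)) break
      pos <- offs[live] + f + 1L
      prev <- pos - 1L
      p <- reflectIntoGeometry(config@geometry,
                               x[prev] + dx[pos], y[prev] + dy[pos])
      x[pos] <- p[, 1]
      y[pos] <- p[, 2]
    }
  }

  if (config@locErrorSd > 0) {
    x <- x + stats::rnorm(total, sd = config@locErrorSd)
    y <- y + stats::rnorm(total, sd = config@locErrorSd)
  }

  trackSet(data.frame(track_id = id, frame = frame, x = x, y = y,
                      state = state),
           frameInterval = dt, condition = condition)
}

#' Simulate dwell durations from a two-exponential mixture
#'
#' Durations are drawn from `Exp(tau1)` with probability `p1` and from
#' `Exp(tau2)` otherwise, then right-discretized (rounded up) to whole
#' multiples of the frame interval: an event observed over k frames has
#' duration `k * frameInterval`.
#'
#' @param p1 mixing fraction of the `tau1` component, in [0, 1].
#' @param tau1,tau2 time constants, s.
#' @param n number of durations.
#' @param frameInterval frame interval, s; 0 disables discretization.
#' @param seed integer RNG seed.
#' @return numeric vector of durations (s).
#' @examples
#' d <- simulateDwellDurations(0.347, 0.19, 0.76, 1000, 0.024, seed = 1)
#' range(d %% 0.024)
#' @export
simulateDwellDurations <- function(p1, tau1, tau2, n, frameInterval,
                                   seed = 1L) {
  if (n <= 0) stop("n must be positive")
  if (tau1 <= 0 || tau2 <= 0) stop("time constants must be positive")
  if (p1 < 0 || p1 > 1) stop("p1 must lie in [0, 1]")
  set.seed(as.integer(seed))
  comp <- stats::rbinom(n, 1L, 1 - p1) + 1L
  tau <- c(tau1, tau2)[comp]
  d <- stats::rexp(n, rate = 1) * tau
  if (frameInterval > 0)
    d <- ceiling(d / frameInterval) * frameInterval
  d[d > 0]
}

#' Simulate squared frame-to-frame displacements from a diffusive mixture
#'
#' For planar Brownian motion the squared displacement over one frame
#' is exponential with mean `4 D dt`; a multi-state population is a
#' mixture of such exponentials. This samples directly from that law,
#' which is the ground truth the cumulative-distribution mixture fit
#' assumes.
#'
#' @param fractions population fractions (sum to 1).
#' @param D per-component diffusion coefficients, um^2/s.
#' @param frameInterval frame interval, s.
#' @param n number of displacements.
#' @param seed integer RNG seed.
#' @return numeric vector of squared displacements (um^2), with the
#'   generating component index in attribute `state`.
#' @export
simulateSquaredDisplacements <- function(fractions, D, frameInterval, n,
                                         seed = 1L) {
  if (length(fractions) != length(D))
    stop("fractions and D must have equal length")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  set.seed(as.integer(seed))
  comp <- sample.int(length(D), n, replace = TRUE, prob = fractions)
  sqd <- stats::rexp(n) * (4 * D[comp] * frameInterval)
  attr(sqd, "state") <- comp
  sqd
}

#' Simulate a raw FRAP measurement table
#'
#' Generates the per-frame region-of-interest measurements that
#' [normalizeFrap()] consumes: a pre-bleach plateau, an instantaneous
#' bleach to a floor, a blanked interval up to the reference anchor
#' (emulating the photoswitching window that the normalization
#' excludes), and a recovery following `I(t) = A (1 - exp(-tau t))`
#' with `t` measured from the anchor. The whole-cell channel decays as
#' `exp(-acqBleachRate t)` to emulate acquisition bleaching, which the
#' focus/cell CTCF ratio cancels.
#'
#' @param A mobile fraction in [0, 1].
#' @param tau recovery rate parameter, 1/s.
#' @param preFrames,postFrames number of frames before/after the bleach.
#' @param interval frame interval, s (20 s in the experiments modelled).
#' @param acqBleachRate acquisition photobleaching rate, 1/s.
#' @param noiseSd Gaussian noise sd on the normalized-recovery scale.
#' @param seed integer RNG seed.
#' @param refOffset reference anchor offset after the bleach, s.
#' @param bleachDepth focus/cell CTCF ratio remaining at the anchor,
#'   relative to pre-bleach.
#' @return `data.frame` with columns `time_s` (relative to bleach),
#'   `roi_integrated_density`, `roi_area`, `background_mean`,
#'   `cell_integrated_density`, `cell_area`.
#' @examples
#' head(simulateFrapSeries(A = 0.8, tau = 0.05, noiseSd = 0))
#' @export
simulateFrapSeries <- function(A, tau, preFrames = 5L, postFrames = 30L,
                               interval = 20, acqBleachRate = 0,
                               noiseSd = 0, seed = 1L,
                               refOffset = interval, bleachDepth = 0.2) {
  if (A < 0 || A > 1) stop("A must lie in [0, 1]")
  if (tau <= 0) stop("tau must be positive")
  if (interval <= 0) stop("interval must be positive")
  set.seed(as.integer(seed))

  tPre <- -rev(seq_len(preFrames)) * interval
  tPost <- (seq_len(postFrames) - 1L) * interval
  t <- c(tPre, tPost)

  ratio <- ifelse(t < 0, 1,
           ifelse(t < refOffset, bleachDepth,
                  bleachDepth +
                    (1 - bleachDepth) * A * (1 - exp(-tau * (t - refOffset)))))
  if (noiseSd > 0)
    ratio <- ratio + stats::rnorm(length(t), sd = noiseSd * (1 - bleachDepth))

  cell0 <- 1e5
  focusShare <- 0.3
  roiArea <- 20
  cellArea <- 200
  bg <- 50
  cellCtcf <- cell0 * exp(-acqBleachRate * (t - t[1]))
  focusCtcf <- focusShare * ratio * cellCtcf

  data.frame(time_s = t,
             roi_integrated_density = focusCtcf + roiArea * bg,
             roi_area = roiArea,
             background_mean = bg,
             cell_integrated_density = cellCtcf + cellArea * bg,
             cell_area = cellArea)
}
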