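## Confinement (dwell) event detection at a fixed radius, two-component
## exponential survival analysis, and confinement heat maps.

#' Detect confinement (dwell) events
#'
#' Scans each track with a fixed confinement radius (97 nm in the
#' experiments modelled here): an event opens at the first
#' localization and grows while every subsequent localization lies
#' within `radius` of the running centroid of the event's members
#' (`rule = "anchor"` measures from the event's first localization
#' instead). The first localization breaking the radius closes the
#' event and starts a new candidate. Events spanning fewer than
#' `minEventFrames` frames are discarded; events truncated by the end
#' of a track are flagged censored.
#'
#' @param ts a filtered [TrackSet-class].
#' @param radius confinement radius, um (default 0.097).
#' @param minEventFrames minimum event length in frames (default 3).
#' @param rule `"centroid"` (default; robust to localization noise) or
#'   `"anchor"`.
#' @return `data.frame` with columns `track_id`, `start_frame`,
#'   `n_frames`, `duration_s`, `censored`, `anchor_x`, `anchor_y`.
#' @export
detectDwellEvents <- function(ts, radius = 0.097, minEventFrames = 3L,
                              rule = c("centroid", "anchor")) {
  if (radius <= 0) stop("radius must be positive")
  rule <- match.arg(rule)
  dt <- ts@frameInterval
  out <- list()
  for (d in split(ts@tracks[c("track_id", "frame", "x", "y")],
                  ts@tracks$track_id)) {
    n <- nrow(d)
    start <- 1L
    sx <- d$x[1]
    sy <- d$y[1]
    m <- 1L
    close_event <- function(i, start, m, censored) {
      nf <- d$frame[i] - d$frame[start] + 1L
      if (nf >= minEventFrames)
        data.frame(start_frame = d$frame[start], n_frames = nf,
                   duration_s = nf * dt, censored = censored,
                   anchor_x = sx / m, anchor_y = sy / m)
      else NULL
    }
    events <- list()
    i <- 2L
    while (i <= n) {
      cx <- if (rule == "centroid") sx / m else d$x[start]
      cy <- if (rule == "centroid") sy / m else d$y[start]
      if (sqrt((d$x[i] - cx)^2 + (d$y[i] - cy)^2) <= radius) {
        sx <- sx + d$x[i]
        sy <- sy + d$y[i]
        m <- m + 1L
        i <- i + 1L
      } else {
        ev <- close_event(i - 1L, start, m, censored = FALSE)
        if (!is.null(ev)) events[[length(events) + 1L]] <- ev
        start <- i
        sx <- d$x[i]
        sy <- d$y[i]
        m <- 1L
        i <- i + 1L
      }
    }
    ev <- close_event(n, start, m, censored = TRUE)
    if (!is.null(ev)) events[[length(events) + 1L]] <- ev
    if (length(events)) {
      ev <- do.call(rbind, events)
      ev$track_id <- rep(d$track_id[1], nrow(ev))
      out[[length(out) + 1L]] <- ev
    }
  }
  if (!length(out))
    return(data.frame(track_id = character(), start_frame = integer(),
                      n_frames = integer(), duration_s = numeric(),
                      censored = logical(), anchor_x = numeric(),
                      anchor_y = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("track_id", "start_frame", "n_frames", "duration_s", "censored",
        "anchor_x", "anchor_y")]
}

#' Dwell-time survival function
#'
#' `S(t)`: the fraction of dwell events lasting at least `t`, evaluated
#' at whole multiples of the frame interval. Censored events (tracks
#' ending while confined) are included by default, matching the
#' "confined for at least this long" reading of the survival function.
#'
#' @param events the `data.frame` from [detectDwellEvents()], or a
#'   numeric vector of durations (s).
#' @param frameInterval frame interval, s (required for a duration
#'   vector; taken from the grid otherwise).
#' @param censoredPolicy `"include"` (default) or `"exclude"`.
#' @param minEvents required minimum number of events.
#' @return `data.frame` with columns `time_s` and `surv`; the number of
#'   events is carried in attribute `nEvents`, the frame interval in
#'   attribute `frameInterval`.
#' @export
dwellSurvival <- function(events, frameInterval = NULL,
                          censoredPolicy = c("include", "exclude"),
                          minEvents = 50L) {
  censoredPolicy <- match.arg(censoredPolicy)
  if (is.data.frame(events)) {
    if (censoredPolicy == "exclude")
      events <- events[!events$censored, , drop = FALSE]
    dur <- events$duration_s
  } else dur <- as.numeric(events)
  if (!length(dur)) stop("no dwell events to build a survival curve from")
  if (length(dur) < minEvents)
    stop(sprintf("fewer than %d dwell events (%d)", minEvents, length(dur)))
  if (is.null(frameInterval)) {
    gaps <- diff(sort(unique(dur)))
    frameInterval <- if (length(gaps)) min(gaps) else dur[1]
  }
  kmax <- ceiling(max(dur) / frameInterval + 1e-9)
  t <- seq_len(kmax) * frameInterval
  s <- vapply(t, function(ti) mean(dur >= ti - 1e-9), numeric(1))
  out <- data.frame(time_s = t, surv = s)
  attr(out, "nEvents") <- length(dur)
  attr(out, "frameInterval") <- frameInterval
  out
}

# biexponential survival model; t0 is the discretization offset
survivalModel <- function(t, p, tau1, tau2, t0) {
  p * exp(-(t - t0) / tau1) + (1 - p) * exp(-(t - t0) / tau2)
}

#' Fit a two-component exponential survival model
#'
#' Least-squares fit of
#' `S(t) = p1 exp(-t/tau1) + p2 exp(-t/tau2)`, `p1 + p2 = 1`, to the
#' dwell-time survival curve, with multi-start optimization. Because
#' durations are right-discretized to whole frames, the probability of
#' lasting at least k frames equals the continuous survival at
#' (k - 1) frame intervals; the model is therefore evaluated with a
#' one-frame offset (`discretizationOffset = TRUE`), without which the
#' time constants carry an `exp(dt/tau)` bias. Standard errors come
#' from a bootstrap over events when raw durations are supplied.
#'
#' @param surv survival curve from [dwellSurvival()] (or any
#'   `data.frame` with `time_s` and `surv`), with at least 5 support
#'   points.
#' @param frameInterval frame interval, s; defaults to the curve's
#'   `frameInterval` attribute or grid spacing.
#' @param discretizationOffset evaluate the model at `t - dt` (default
#'   TRUE).
#' @param nStarts number of multi-start optimizations.
#' @param nBoot bootstrap replicates (0 disables; requires
#'   `durations`).
#' @param durations raw durations for the bootstrap.
#' @param seed RNG seed for starts and bootstrap.
#' @return a [DwellFit-class] with `tau` sorted ascending.
#' @examples
#' d <- simulateDwellDurations(0.35, 0.2, 0.8, 2000, 0.024, seed = 3)
#' s <- dwellSurvival(d, frameInterval = 0.024)
#' fitSurvivalBiexponential(s)
#' @export
fitSurvivalBiexponential <- function(surv, frameInterval = NULL,
                                     discretizationOffset = TRUE,
                                     nStarts = 8L, nBoot = 0L,
                                     durations = NULL, seed = 1L) {
  if (nrow(surv) < 5L)
    stop("survival curve needs at least 5 support points")
  if (is.null(frameInterval))
    frameInterval <- attr(surv, "frameInterval")
  if (is.null(frameInterval))
    frameInterval <- min(diff(sort(unique(surv$time_s))))
  t0 <- if (discretizationOffset) frameInterval else 0

  fitOnce <- function(t, s, starts) {
    obj <- function(par) {
      p <- stats::plogis(par[1])
      sum((survivalModel(t, p, exp(par[2]), exp(par[3]), t0) - s)^2)
    }
    best <- NULL
    for (st in starts) {
      opt <- try(stats::optim(st, obj, method = "Nelder-Mead",
                              control = list(maxit = 2000,
                                             reltol = 1e-12)),
                 silent = TRUE)
      if (inherits(opt, "try-error")) next
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (is.null(best)) stop("biexponential survival fit did not converge")
    tau <- exp(best$par[2:3])
    p <- c(stats::plogis(best$par[1]), 1 - stats::plogis(best$par[1]))
    ord <- order(tau)
    list(tau = tau[ord], p = p[ord])
  }

  # crude single-exponential scale from the curve for the starts
  tauScale <- {
    below <- which(surv$surv <= exp(-1))
    if (length(below)) surv$time_s[below[1]] else max(surv$time_s) / 2
  }
  set.seed(as.integer(seed))
  starts <- lapply(seq_len(nStarts), function(i) {
    if (i == 1L) c(0, log(tauScale / 3), log(tauScale * 2))
    else c(stats::rnorm(1),
           log(tauScale * exp(stats::runif(1, log(0.05), log(1)))),
           log(tauScale * exp(stats::runif(1, log(1), log(20)))))
  })
  fit <- fitOnce(surv$time_s, surv$surv, starts)

  seTau <- rep(NA_real_, 2)
  seP <- rep(NA_real_, 2)
  if (nBoot > 0L && !is.null(durations)) {
    bt <- matrix(NA_real_, nBoot, 2)
    bp <- matrix(NA_real_, nBoot, 2)
    for (b in seq_len(nBoot)) {
      dd <- durations[sample.int(length(durations), replace = TRUE)]
      sb <- dwellSurvival(dd, frameInterval, minEvents = 1L)
      fb <- try(fitOnce(sb$time_s, sb$surv,
                        list(c(stats::qlogis(min(max(fit$p[1], 0.01),
                                                 0.99)),
                               log(fit$tau)))), silent = TRUE)
      if (inherits(fb, "try-error")) next
      bt[b, ] <- fb$tau
      bp[b, ] <- fb$p
    }
    seTau <- apply(bt, 2, stats::sd, na.rm = TRUE)
    seP <- apply(bp, 2, stats::sd, na.rm = TRUE)
  }

  nEvents <- attr(surv, "nEvents")
  if (is.null(nEvents)) nEvents <- NA_integer_
  new("DwellFit", tau = fit$tau, p = fit$p, seTau = seTau, seP = seP,
      nEvents = as.integer(nEvents), frameInterval = frameInterval)
}

#' Confinement heat map in normalized cell coordinates
#'
#' Maps the localizations of confined-labelled tracks into normalized
#' half-cell coordinates (long axis |x| / (L/2) in [0, 1], short axis
#' y / (W/2) in [-1, 1]) and applies fourfold mirror averaging: the
#' long axis is folded by the absolute value and each point enters at
#' +/- its short-axis coordinate with weight 1/2, so the binned counts
#' still sum to the number of mapped localizations. A kernel-smoothed
#' density over the same grid is returned alongside.
#'
#' @param ts a labelled [TrackSet-class] (see [classifyTracks()]).
#' @param geometry the [CellGeometry-class] of the (averaged) cell.
#' @param bins bins along the long and short axis.
#' @param label track label selecting the mapped population.
#' @return a [ConfinementMap-class].
#' @export
confinementHeatmap <- function(ts, geometry, bins = c(20L, 20L),
                               label = "confined") {
  tr <- ts@tracks
  if (!"label" %in% names(tr))
    stop("tracks carry no mobility labels; run classifyTracks() first")
  tr <- tr[!is.na(tr$label) & tr$label == label, , drop = FALSE]
  nx <- bins[1]
  ny <- if (length(bins) > 1L) bins[2] else bins[1]
  xb <- seq(0, 1, length.out = nx + 1L)
  yb <- seq(-1, 1, length.out = ny + 1L)
  xm <- (xb[-1] + xb[-(nx + 1L)]) / 2
  ym <- (yb[-1] + yb[-(ny + 1L)]) / 2
  if (!nrow(tr)) {
    warning("no localizations with the requested label; empty map")
    return(new("ConfinementMap", counts = matrix(0, nx, ny),
               density = matrix(0, nx, ny), xMids = xm, yMids = ym,
               nPoints = 0L))
  }
  xn <- pmin(abs(tr$x) / (geometry@length / 2), 1)
  yn <- pmin(pmax(tr$y / (geometry@width / 2), -1), 1)

  binCounts <- function(xs, ys, w) {
    xi <- pmin(pmax(findInterval(xs, xb, rightmost.closed = TRUE), 1L), nx)
    yi <- pmin(pmax(findInterval(ys, yb, rightmost.closed = TRUE), 1L), ny)
    m <- matrix(0, nx, ny)
    for (i in seq_along(xs)) m[xi[i], yi[i]] <- m[xi[i], yi[i]] + w
    m
  }
  counts <- binCounts(xn, yn, 0.5) + binCounts(xn, -yn, 0.5)

  # mirror padding across the fold axis (x = 0) so the kernel density
  # is unbiased at the symmetry boundary; the outline end (x = 1) is a
  # true support edge and is not padded
  kd <- MASS::kde2d(c(xn, xn, -xn, -xn), c(yn, -yn, yn, -yn),
                    n = c(nx, ny), lims = c(0, 1, -1, 1))
  new("ConfinementMap", counts = counts, density = kd$z, xMids = xm,
      yMids = ym, nPoints = as.integer(nrow(tr)))
}
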