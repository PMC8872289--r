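#' @import methods
NULL

#' Cell geometry for simulation and heat maps
#'
#' Planar outline of a bacterial cell as seen in TIRF: either a rod
#' (2D spherocylinder: rectangle capped by two semicircles) or a sphere
#' (disc), centred at the origin with the long axis along x.
#'
#' @slot shape `"rod"` or `"sphere"`.
#' @slot length cap-to-cap long-axis extent in micrometres.
#' @slot width cell diameter in micrometres (equals `length` for spheres).
#'
#' @seealso [cellGeometry()]
#' @exportClass CellGeometry
setClass("CellGeometry",
  slots = c(shape = "character", length = "numeric", width = "numeric"))

setValidity("CellGeometry", function(object) {
  msg <- character()
  if (!(length(object@shape) == 1L && object@shape %in% c("rod", "sphere")))
    msg <- c(msg, "shape must be 'rod' or 'sphere'")
  if (length(object@length) != 1L || length(object@width) != 1L ||
      !is.finite(object@length) || !is.finite(object@width))
    msg <- c(msg, "length and width must be finite scalars")
  else {
    if (!(object@width > 0))
      msg <- c(msg, "width must be > 0")
    if (object@length < object@width)
      msg <- c(msg, "length must be >= width")
    if (identical(object@shape, "sphere") &&
        abs(object@length - object@width) > 1e-12)
      msg <- c(msg, "for a sphere, length must equal width")
  }
  if (length(msg)) msg else TRUE
})

#' Simulation configuration for multi-state Brownian tracks
#'
#' Bundles the generative model of the track simulator: up to three
#' diffusive components with fixed per-track state, frame interval,
#' localization error, photobleaching-limited track length, and an
#' optional bounding [CellGeometry-class] with reflecting walls.
#'
#' @slot D per-component diffusion coefficients, um^2/s.
#' @slot fractions per-component population fractions summing to 1.
#' @slot frameInterval acquisition frame interval in seconds.
#' @slot locErrorSd localization error standard deviation per axis, um.
#' @slot bleachProb per-frame probability that a track terminates
#'   (track lengths are geometric with mean `1/bleachProb`).
#' @slot nTracks number of tracks to generate.
#' @slot geometry a [CellGeometry-class] or `NULL` for unbounded motion.
#' @slot switchProb per-frame probability of re-drawing the diffusive
#'   state (Markov switching); 0 (the default) keeps states fixed per
#'   molecule, matching the population interpretation of the mixture fit.
#' @slot seed integer RNG seed.
#'
#' @seealso [simConfig()], [simulateTracks()]
#' @exportClass SimConfig
setClass("SimConfig",
  slots = c(D = "numeric", fractions = "numeric", frameInterval = "numeric",
            locErrorSd = "numeric", bleachProb = "numeric",
            nTracks = "integer", geometry = "ANY", switchProb = "numeric",
            seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@D) < 1L || length(object@D) != length(object@fractions))
    msg <- c(msg, "D and fractions must be non-empty and of equal length")
  if (any(object@D < 0)) msg <- c(msg, "diffusion coefficients must be >= 0")
  if (any(object@fractions < 0) ||
      abs(sum(object@fractions) - 1) > 1e-9)
    msg <- c(msg, "fractions must be non-negative and sum to 1 (tol 1e-9)")
  if (!(object@frameInterval > 0)) msg <- c(msg, "frameInterval must be > 0")
  if (object@locErrorSd < 0) msg <- c(msg, "locErrorSd must be >= 0")
  if (object@bleachProb < 0 || object@bleachProb >= 1)
    msg <- c(msg, "bleachProb must be in [0, 1)")
  if (object@nTracks < 1L) msg <- c(msg, "nTracks must be >= 1")
  if (!is.null(object@geometry) && !is(object@geometry, "CellGeometry"))
    msg <- c(msg, "geometry must be NULL or a CellGeometry")
  if (object@switchProb < 0 || object@switchProb > 1)
    msg <- c(msg, "switchProb must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Set of single-molecule tracks
#'
#' Container for an SPT experiment: one table of localizations
#' (columns `track_id`, `frame`, `x`, `y` in micrometres, plus optional
#' `state` ground-truth component index and `label` classification),
#' the acquisition frame interval, and a condition label.
#'
#' @slot tracks `data.frame` of localizations, ordered by track then frame.
#' @slot frameInterval frame interval in seconds.
#' @slot condition condition label (strain/treatment).
#'
#' @seealso [trackSet()], [simulateTracks()], [readTracks()]
#' @exportClass TrackSet
setClass("TrackSet",
  slots = c(tracks = "data.frame", frameInterval = "numeric",
            condition = "character"))

setValidity("TrackSet", function(object) {
  msg <- character()
  need <- c("track_id", "frame", "x", "y")
  if (!all(need %in% names(object@tracks)))
    msg <- c(msg, paste("tracks must have columns:",
                        paste(need, collapse = ", ")))
  if (!(length(object@frameInterval) == 1L && object@frameInterval > 0))
    msg <- c(msg, "frameInterval must be a positive scalar")
  if (!(length(object@condition) == 1L && nzchar(object@condition)))
    msg <- c(msg, "condition must be a non-empty string")
  if (!length(msg) && nrow(object@tracks)) {
    tr <- object@tracks
    if (!is.numeric(tr$frame) || anyNA(tr$frame))
      msg <- c(msg, "frame must be numeric and non-missing")
    else {
      d <- unlist(tapply(tr$frame, tr$track_id, function(f) diff(f)),
                  use.names = FALSE)
      if (length(d) && any(d <= 0))
        msg <- c(msg, "frames must be strictly increasing within each track")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Ensemble mean-squared-displacement curve
#'
#' MSD evaluated at a handful of short lag times (by default four:
#' 1..4 frame intervals), pooled over all eligible displacement pairs.
#'
#' @slot lags lag times in seconds, strictly increasing.
#' @slot msd mean squared displacement per lag, um^2.
#' @slot nPairs number of displacement pairs per lag.
#' @slot frameInterval frame interval in seconds.
#' @exportClass MsdCurve
setClass("MsdCurve",
  slots = c(lags = "numeric", msd = "numeric", nPairs = "integer",
            frameInterval = "numeric"))

setValidity("MsdCurve", function(object) {
  msg <- character()
  n <- length(object@lags)
  if (length(object@msd) != n || length(object@nPairs) != n)
    msg <- c(msg, "lags, msd and nPairs must have equal length")
  if (n > 1 && any(diff(object@lags) <= 0))
    msg <- c(msg, "lags must be strictly increasing")
  if (any(object@msd < 0)) msg <- c(msg, "msd must be >= 0")
  if (n > 0 && any(object@nPairs < 1L)) msg <- c(msg, "nPairs must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Linear MSD fit
#'
#' Ordinary least-squares fit of MSD on lag time with a free intercept;
#' for planar Brownian motion the slope is `4 D` and the intercept
#' absorbs the `4 sigma^2` localization-error offset.
#'
#' @slot D apparent diffusion coefficient, um^2/s (slope / 4).
#' @slot intercept fitted intercept, um^2 (may be negative).
#' @slot rSquared coefficient of determination.
#' @exportClass MsdFit
setClass("MsdFit",
  slots = c(D = "numeric", intercept = "numeric", rSquared = "numeric"))

#' Multi-state diffusion mixture
#'
#' Result of the global squared-displacement (jump distance) mixture
#' fit: up to three diffusion coefficients shared across conditions and
#' per-condition population fractions.
#'
#' @slot D shared diffusion coefficients, um^2/s, sorted ascending
#'   (confined < slow < fast).
#' @slot fractions matrix of fractions, conditions in rows, components
#'   in columns; each row sums to 1.
#' @slot seD bootstrap standard errors of `D` (NA when not bootstrapped).
#' @slot seFractions bootstrap standard errors of `fractions`.
#' @slot nSteps named count of squared displacements per condition.
#' @slot frameInterval frame interval in seconds.
#' @exportClass DiffusionMixture
setClass("DiffusionMixture",
  slots = c(D = "numeric", fractions = "matrix", seD = "numeric",
            seFractions = "matrix", nSteps = "numeric",
            frameInterval = "numeric"))

setValidity("DiffusionMixture", function(object) {
  msg <- character()
  k <- length(object@D)
  if (k < 1L || k > 3L) msg <- c(msg, "between 1 and 3 components required")
  if (k > 1 && any(diff(object@D) < 0))
    msg <- c(msg, "D must be sorted ascending")
  if (ncol(object@fractions) != k)
    msg <- c(msg, "fractions must have one column per component")
  rs <- rowSums(object@fractions)
  if (any(abs(rs - 1) > 1e-6))
    msg <- c(msg, "fractions must sum to 1 per condition (tol 1e-6)")
  if (any(object@fractions < -1e-9 | object@fractions > 1 + 1e-9))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Two-component dwell-time survival fit
#'
#' Parameters of the biexponential survival model
#' `S(t) = p1 exp(-t/tau1) + p2 exp(-t/tau2)` with `p1 + p2 = 1`,
#' fitted to the dwell-time survival function.
#'
#' @slot tau time constants in seconds, sorted ascending.
#' @slot p fractions attached to `tau`, summing to 1.
#' @slot seTau bootstrap standard errors of `tau` (NA when not bootstrapped).
#' @slot seP bootstrap standard errors of `p`.
#' @slot nEvents number of dwell events fitted.
#' @slot frameInterval frame interval in seconds.
#' @exportClass DwellFit
setClass("DwellFit",
  slots = c(tau = "numeric", p = "numeric", seTau = "numeric",
            seP = "numeric", nEvents = "integer", frameInterval = "numeric"))

setValidity("DwellFit", function(object) {
  msg <- character()
  if (length(object@tau) != 2L || length(object@p) != 2L)
    msg <- c(msg, "tau and p must have length 2")
  else {
    if (any(object@tau <= 0)) msg <- c(msg, "tau must be > 0")
    if (object@tau[1] > object@tau[2]) msg <- c(msg, "tau must be sorted")
    if (abs(sum(object@p) - 1) > 1e-6)
      msg <- c(msg, "p must sum to 1 (tol 1e-6)")
  }
  if (length(msg)) msg else TRUE
})

#' Normalized FRAP recovery curve
#'
#' Per-frame ratio of focus to whole-cell corrected total cell
#' fluorescence (CTCF), affinely rescaled so the pre-bleach mean maps
#' to 1 and the frame `refOffset` seconds after the bleach maps to 0.
#' Times in `data$t_fit` are measured from the reference anchor; only
#' frames with `t_fit >= 0` enter the recovery fit.
#'
#' @slot data `data.frame` with columns `time_s` (relative to bleach),
#'   `ratio`, `normalized`, `t_fit`, `phase`.
#' @slot anchors numeric: pre-bleach mean ratio and reference-frame ratio.
#' @slot refOffset reference anchor offset after the bleach, seconds.
#' @exportClass FrapCurve
setClass("FrapCurve",
  slots = c(data = "data.frame", anchors = "numeric", refOffset = "numeric"))

#' Exponential FRAP recovery fit
#'
#' Fit of `I(t) = A (1 - exp(-tau t))` to a normalized FRAP curve,
#' with halftime `t_half = ln(2) / tau`, mobile fraction `A` and
#' immobile fraction `1 - A`.
#'
#' @slot A mobile fraction (plateau); values > 1 are flagged, not clamped.
#' @slot tau fitted rate parameter, 1/s.
#' @slot tHalf recovery halftime, s.
#' @slot immobile immobile fraction `1 - A`.
#' @slot sigma residual standard deviation of the fit.
#' @slot warnings fit-quality warnings (e.g. `A > 1`).
#' @exportClass FrapFit
setClass("FrapFit",
  slots = c(A = "numeric", tau = "numeric", tHalf = "numeric",
            immobile = "numeric", sigma = "numeric", warnings = "character"))

setValidity("FrapFit", function(object) {
  msg <- character()
  if (object@tau <= 0) msg <- c(msg, "tau must be > 0")
  if (abs(object@tHalf * object@tau - log(2)) > 1e-9)
    msg <- c(msg, "tHalf must equal ln(2)/tau")
  if (abs(object@immobile - (1 - object@A)) > 1e-9)
    msg <- c(msg, "immobile must equal 1 - A")
  if (length(msg)) msg else TRUE
})

#' Confinement heat map
#'
#' Localizations of confined-labelled tracks mapped into normalized
#' half-cell coordinates (long axis in [0, 1], short axis in [-1, 1])
#' with fourfold mirror averaging, binned and kernel-smoothed.
#'
#' @slot counts matrix of binned counts (long-axis bins in rows).
#' @slot density kernel-smoothed density on the same grid.
#' @slot xMids,yMids bin midpoints along the normalized axes.
#' @slot nPoints number of localizations mapped.
#' @exportClass ConfinementMap
setClass("ConfinementMap",
  slots = c(counts = "matrix", density = "matrix", xMids = "numeric",
            yMids = "numeric", nPoints = "integer"))

setValidity("ConfinementMap", function(object) {
  if (object@nPoints > 0 &&
      abs(sum(object@counts) - object@nPoints) > 1e-9)
    "sum of counts must equal nPoints"
  else TRUE
})
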