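#' Accessors for DynaTrack classes
#'
#' Small accessor family: `tracks()` returns the localization table of a
#' [TrackSet-class]; `frameInterval()` the acquisition interval in
#' seconds; `condition()` the condition label; `nTracks()` the number of
#' distinct tracks; `diffusionCoefficients()` and `fractions()` the
#' shared diffusion constants and per-condition population fractions of
#' a [DiffusionMixture-class]; `dwellParameters()` the `(tau, p)` table
#' of a [DwellFit-class]; `mobileFraction()` the plateau of a
#' [FrapFit-class].
#'
#' @param object an object of the documented class.
#' @return the slot content described above.
#' @name accessors
#' @aliases tracks frameInterval condition nTracks diffusionCoefficients
#'   fractions dwellParameters mobileFraction
NULL

#' @rdname accessors
#' @export
setGeneric("tracks", function(object) standardGeneric("tracks"))

#' @rdname accessors
#' @export
setGeneric("frameInterval",
  function(object) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))

#' @rdname accessors
#' @export
setGeneric("nTracks", function(object) standardGeneric("nTracks"))

#' @rdname accessors
#' @export
setGeneric("diffusionCoefficients",
  function(object) standardGeneric("diffusionCoefficients"))

#' @rdname accessors
#' @export
setGeneric("fractions", function(object) standardGeneric("fractions"))

#' @rdname accessors
#' @export
setGeneric("dwellParameters",
  function(object) standardGeneric("dwellParameters"))

#' @rdname accessors
#' @export
setGeneric("mobileFraction",
  function(object) standardGeneric("mobileFraction"))

#' @rdname accessors
setMethod("tracks", "TrackSet", function(object) object@tracks)

#' @rdname accessors
setMethod("frameInterval", "TrackSet", function(object) object@frameInterval)

#' @rdname accessors
setMethod("frameInterval", "DiffusionMixture",
  function(object) object@frameInterval)

#' @rdname accessors
setMethod("frameInterval", "DwellFit", function(object) object@frameInterval)

#' @rdname accessors
setMethod("condition", "TrackSet", function(object) object@condition)

#' @rdname accessors
setMethod("nTracks", "TrackSet",
  function(object) length(unique(object@tracks$track_id)))

#' @rdname accessors
setMethod("diffusionCoefficients", "DiffusionMixture",
  function(object) object@D)

#' @rdname accessors
setMethod("fractions", "DiffusionMixture", function(object) object@fractions)

#' @rdname accessors
setMethod("dwellParameters", "DwellFit", function(object)
  data.frame(component = c("short", "long"), tau_s = object@tau,
             fraction = object@p, se_tau = object@seTau, se_p = object@seP))

#' @rdname accessors
setMethod("mobileFraction", "FrapFit", function(object) object@A)

setMethod("show", "CellGeometry", function(object) {
  cat(sprintf("CellGeometry: %s, length %.3g um x width %.3g um\n",
              object@shape, object@length, object@width))
})

setMethod("show", "TrackSet", function(object) {
  cat(sprintf(
    "TrackSet '%s': %d tracks, %d localizations, frame interval %g s\n",
    object@condition, nTracks(object), nrow(object@tracks),
    object@frameInterval))
})

setMethod("show", "MsdCurve", function(object) {
  cat(sprintf("MsdCurve: %d lags (%g..%g s)\n", length(object@lags),
              min(object@lags), max(object@lags)))
  print(data.frame(lag_s = object@lags, msd_um2 = object@msd,
                   n_pairs = object@nPairs), row.names = FALSE)
})

setMethod("show", "MsdFit", function(object) {
  cat(sprintf("MsdFit: D = %.4g um^2/s, intercept = %.4g um^2, R^2 = %.4f\n",
              object@D, object@intercept, object@rSquared))
})

setMethod("show", "DiffusionMixture", function(object) {
  lbl <- componentLabels(length(object@D))
  cat(sprintf("DiffusionMixture: %d components, shared D (um^2/s): %s\n",
              length(object@D),
              paste(sprintf("%s=%.4g", lbl, object@D), collapse = ", ")))
  fr <- object@fractions
  colnames(fr) <- lbl
  cat("Fractions per condition:\n")
  print(round(fr, 4))
})

setMethod("show", "DwellFit", function(object) {
  cat(sprintf(
    "DwellFit (%d events): tau1 = %.3g s (%.1f%%), tau2 = %.3g s (%.1f%%)\n",
    object@nEvents, object@tau[1], 100 * object@p[1], object@tau[2],
    100 * object@p[2]))
})

setMethod("show", "FrapCurve", function(object) {
  cat(sprintf(
    "FrapCurve: %d frames (%d recovery), anchors pre = %.4g, +%gs = %.4g\n",
    nrow(object@data), sum(object@data$t_fit >= 0, na.rm = TRUE),
    object@refOffset, object@anchors[1], object@anchors[2]))
})

setMethod("show", "FrapFit", function(object) {
  cat(sprintf(
    "FrapFit: mobile A = %.3f, immobile = %.3f, tau = %.4g 1/s, t1/2 = %.3g s\n",
    object@A, object@immobile, object@tau, object@tHalf))
  if (length(object@warnings))
    cat("warnings:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "ConfinementMap", function(object) {
  cat(sprintf("ConfinementMap: %d x %d bins, %d localizations\n",
              length(object@xMids), length(object@yMids), object@nPoints))
})

# canonical mobility labels by ascending D
componentLabels <- function(k) {
  switch(k, "confined", c("confined", "fast"), c("confined", "slow", "fast"))
}
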