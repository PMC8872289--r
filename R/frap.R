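## FRAP quantification: CTCF, anchor normalization, exponential
## recovery fit with mobile/immobile fractions, and group comparisons.

#' Corrected total cell fluorescence
#'
#' `CTCF = integrated density - area x mean background`, the standard
#' background correction for region-of-interest intensity measurements.
#'
#' @param integratedDensity summed ROI intensity.
#' @param area ROI area (same length or scalar).
#' @param backgroundMean mean background intensity per unit area.
#' @return numeric CTCF values.
#' @examples
#' computeCTCF(1000, 100, 2)  # 800
#' @export
computeCTCF <- function(integratedDensity, area, backgroundMean) {
  if (any(area < 0)) stop("area must be non-negative")
  integratedDensity - area * backgroundMean
}

#' Normalize a FRAP series to pre-bleach / post-bleach anchors
#'
#' Computes the per-frame ratio of focus CTCF to whole-cell CTCF (the
#' ratio cancels acquisition photobleaching), then rescales affinely so
#' that the mean pre-bleach ratio maps to 1 and the ratio at
#' `refOffset` seconds after the bleach maps to 0. Frames between the
#' bleach and the reference anchor are excluded from fitting (the
#' anchor is placed late enough to avoid fluorophore photoswitching
#' artefacts); the fitting time origin is the anchor frame.
#'
#' @param frapData `data.frame` with columns `time_s` (seconds relative
#'   to the bleach; pre-bleach frames negative), `roi_integrated_density`,
#'   `roi_area`, `background_mean`, `cell_integrated_density` and
#'   optionally `cell_area` (whole-cell background correction).
#' @param refOffset reference anchor offset after the bleach, s
#'   (default 20).
#' @return a [FrapCurve-class].
#' @export
normalizeFrap <- function(frapData, refOffset = 20) {
  need <- c("time_s", "roi_integrated_density", "roi_area",
            "background_mean", "cell_integrated_density")
  missing <- setdiff(need, names(frapData))
  if (length(missing))
    stop("FRAP table missing column(s): ", paste(missing, collapse = ", "))
  t <- frapData$time_s
  focus <- computeCTCF(frapData$roi_integrated_density, frapData$roi_area,
                       frapData$background_mean)
  cell <- if ("cell_area" %in% names(frapData))
    computeCTCF(frapData$cell_integrated_density, frapData$cell_area,
                frapData$background_mean)
  else frapData$cell_integrated_density
  if (any(abs(cell) < .Machine$double.eps))
    stop("whole-cell CTCF is zero in at least one frame")
  ratio <- focus / cell

  pre <- t < 0
  if (!any(pre)) stop("no pre-bleach frames (time_s < 0)")
  spacing <- stats::median(diff(sort(t)))
  refIdx <- which.min(abs(t - refOffset))
  if (abs(t[refIdx] - refOffset) > spacing / 2 + 1e-9)
    stop(sprintf("no frame at the +%g s reference anchor", refOffset))

  preValue <- mean(ratio[pre])
  refValue <- ratio[refIdx]
  if (abs(preValue - refValue) < .Machine$double.eps)
    stop("degenerate anchors: pre-bleach and reference ratios coincide")
  normalized <- (ratio - refValue) / (preValue - refValue)
  tFit <- t - t[refIdx]
  phase <- ifelse(pre, "pre",
           ifelse(tFit < 0, "excluded", "recovery"))

  new("FrapCurve",
      data = data.frame(time_s = t, ratio = ratio,
                        normalized = normalized, t_fit = tFit,
                        phase = phase),
      anchors = c(pre = preValue, ref = refValue),
      refOffset = refOffset)
}

#' Fit the exponential FRAP recovery
#'
#' Nonlinear least squares of `I(t) = A (1 - exp(-tau t))` on the
#' normalized recovery values for `t >= 0` (time measured from the
#' reference anchor). The halftime is `t_half = ln(2) / tau`; the
#' mobile fraction is the plateau `A` and the immobile fraction
#' `1 - A`. `A` is not clamped: values above 1 are flagged as a fit
#' warning rather than an error.
#'
#' @param curve a [FrapCurve-class] (or a `data.frame` with columns
#'   `t_fit` and `normalized`) with at least 5 post-anchor frames.
#' @return a [FrapFit-class].
#' @examples
#' raw <- simulateFrapSeries(A = 0.8, tau = 0.05, noiseSd = 0)
#' fitFrapRecovery(normalizeFrap(raw))
#' @export
fitFrapRecovery <- function(curve) {
  d <- if (is(curve, "FrapCurve")) curve@data else as.data.frame(curve)
  d <- d[d$t_fit >= 0, , drop = FALSE]
  if (nrow(d) < 5L)
    stop("at least 5 post-anchor frames are required")
  tt <- d$t_fit
  yy <- d$normalized

  plateau <- mean(yy[tt >= stats::quantile(tt, 0.7)])
  half <- tt[which(yy >= plateau / 2)[1]]
  tau0 <- if (is.na(half) || half <= 0) 1 / max(tt) else log(2) / half
  fit <- NULL
  for (tauStart in unique(c(tau0, tau0 * c(0.1, 10), 0.01, 0.1))) {
    fit <- try(minpack.lm::nlsLM(
      yy ~ A * (1 - exp(-tau * tt)),
      start = list(A = max(plateau, 0.1), tau = tauStart),
      lower = c(A = -Inf, tau = 1e-10),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (!inherits(fit, "try-error")) break
  }
  if (inherits(fit, "try-error") || is.null(fit))
    stop("FRAP recovery fit did not converge")
  co <- stats::coef(fit)
  if (co[["tau"]] <= 1e-9)
    stop("FRAP fit quality error: recovery rate collapsed to zero")
  warn <- character()
  if (co[["A"]] > 1) warn <- c(warn, "mobile fraction A exceeds 1")
  if (co[["A"]] < 0) warn <- c(warn, "mobile fraction A is negative")
  new("FrapFit", A = unname(co[["A"]]), tau = unname(co[["tau"]]),
      tHalf = log(2) / unname(co[["tau"]]),
      immobile = 1 - unname(co[["A"]]),
      sigma = stats::sigma(fit), warnings = warn)
}

#' Compare recovery halftimes between groups
#'
#' Implements the decision path used for the FRAP statistics: each
#' group is tested for normality (Shapiro-Wilk) and the groups jointly
#' for homoscedasticity (Bartlett). If neither test rejects, the
#' treatments are compared against the control with Dunnett's
#' many-to-one test (one-sided, alternative: true location shift less
#' than 0); otherwise each treatment is compared with the control by a
#' Wilcoxon rank-sum test with continuity correction (same one-sided
#' alternative).
#'
#' @param values numeric outcome (e.g. recovery halftimes, s).
#' @param group group labels; factor levels order the groups.
#' @param control control group label (default: first level).
#' @param alpha significance level for the assumption checks.
#' @return list with elements `path` ("parametric" or "rank"),
#'   `normality` (per-group Shapiro p-values), `homoscedasticity`
#'   (Bartlett p-value), and `comparisons` (`data.frame` of
#'   treatment-vs-control one-sided p-values).
#' @export
compareGroups <- function(values, group, control = NULL, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("at least two groups are required")
  sizes <- table(group)
  if (any(sizes < 3L))
    stop("each group needs at least 3 values")
  if (is.null(control)) control <- levels(group)[1]
  if (!control %in% levels(group)) stop("unknown control group")
  group <- stats::relevel(group, ref = control)
  treatments <- setdiff(levels(group), control)

  # zero-variance groups break the assumption tests; route such data
  # down the rank-based path
  normality <- vapply(levels(group), function(g)
    tryCatch(stats::shapiro.test(values[group == g])$p.value,
             error = function(e) NA_real_), numeric(1))
  homosced <- tryCatch(stats::bartlett.test(values, group)$p.value,
                       error = function(e) NA_real_)

  if (!anyNA(normality) && !is.na(homosced) && !is.nan(homosced) &&
      all(normality > alpha) && homosced > alpha) {
    path <- "parametric"
    fit <- stats::aov(values ~ group,
                      data = data.frame(values = values, group = group))
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"),
                         alternative = "less")
    sm <- summary(gl)
    comparisons <- data.frame(
      treatment = treatments, control = control,
      p_value = as.numeric(sm$test$pvalues),
      test = "Dunnett one-sided")
  } else {
    path <- "rank"
    comparisons <- do.call(rbind, lapply(treatments, function(tr) {
      wt <- stats::wilcox.test(values[group == tr],
                               values[group == control],
                               alternative = "less", correct = TRUE,
                               exact = FALSE)
      data.frame(treatment = tr, control = control, p_value = wt$p.value,
                 test = "Wilcoxon rank-sum one-sided")
    }))
  }
  list(path = path, normality = normality, homoscedasticity = homosced,
       comparisons = comparisons, alpha = alpha)
}
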