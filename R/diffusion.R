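## Squared-displacement and MSD statistics, and the global jump-distance
## mixture decomposition with diffusion constants shared across conditions.

# Indices of eligible pair start positions at `lag` frames within one
# track: all intermediate frames must be present (a displacement across
# a linking gap is not a k-frame jump) and the end point must not be
# the track's last localization (track-ending artifacts).
eligiblePairs <- function(frames, lag) {
  idx <- seq_along(frames)
  end <- match(frames + lag, frames)
  ok <- !is.na(end) & (frames + lag) != frames[length(frames)]
  if (lag > 1L) {
    for (m in seq_len(lag - 1L))
      ok <- ok & !is.na(match(frames + m, frames))
  }
  cbind(start = idx[ok], end = end[ok])
}

#' Squared frame-to-frame displacements of a track set
#'
#' Computes, for every track, the squared Euclidean displacement over
#' exactly `lagFrames` consecutive frames. Pairs spanning a linking gap
#' (missing intermediate frames) are excluded, as is any pair ending at
#' a track's final localization.
#'
#' @param ts a filtered [TrackSet-class].
#' @param lagFrames lag in frames (default 1, the jump-distance lag).
#' @return `data.frame` with columns `condition` and `sqd` (um^2).
#' @seealso [fitSqdMixtureGlobal()]
#' @export
squaredDisplacements <- function(ts, lagFrames = 1L) {
  if (lagFrames < 1L) stop("lagFrames must be >= 1")
  tr <- ts@tracks
  sqd <- unlist(lapply(split(tr[c("frame", "x", "y")], tr$track_id),
                       function(d) {
    if (nrow(d) < 2L) return(numeric())
    pr <- eligiblePairs(d$frame, lagFrames)
    (d$x[pr[, 2]] - d$x[pr[, 1]])^2 + (d$y[pr[, 2]] - d$y[pr[, 1]])^2
  }), use.names = FALSE)
  data.frame(condition = rep(ts@condition, length(sqd)), sqd = sqd)
}

#' Ensemble mean-squared displacement
#'
#' MSD at lags `1..nLags` frame intervals: the mean over all eligible
#' displacement pairs (time-averaged within tracks, pooled across
#' tracks weighted by pair count). Pair eligibility follows
#' [squaredDisplacements()]. Lags with no eligible pairs are omitted
#' with a warning.
#'
#' @param ts a filtered [TrackSet-class].
#' @param nLags number of lags (default 4, i.e. 24/48/72/96 ms at a
#'   24 ms frame interval).
#' @return an [MsdCurve-class].
#' @export
ensembleMSD <- function(ts, nLags = 4L) {
  tr <- ts@tracks
  byTrack <- split(tr[c("frame", "x", "y")], tr$track_id)
  msd <- numeric(0)
  lags <- numeric(0)
  nPairs <- integer(0)
  for (k in seq_len(nLags)) {
    s <- 0
    n <- 0L
    for (d in byTrack) {
      if (nrow(d) < 2L) next
      pr <- eligiblePairs(d$frame, k)
      if (!nrow(pr)) next
      s <- s + sum((d$x[pr[, 2]] - d$x[pr[, 1]])^2 +
                   (d$y[pr[, 2]] - d$y[pr[, 1]])^2)
      n <- n + nrow(pr)
    }
    if (n == 0L) {
      warning(sprintf("no eligible pairs at lag %d; lag omitted", k))
      next
    }
    lags <- c(lags, k * ts@frameInterval)
    msd <- c(msd, s / n)
    nPairs <- c(nPairs, n)
  }
  new("MsdCurve", lags = lags, msd = msd, nPairs = nPairs,
      frameInterval = ts@frameInterval)
}

#' Linear fit of the MSD curve
#'
#' Ordinary least squares of MSD on lag time with a free intercept.
#' For planar Brownian motion `MSD(t) = 4 D t + 4 sigma^2`, so the
#' apparent diffusion coefficient is slope / 4 and the intercept
#' absorbs the localization-error offset (it may be negative and is
#' reported as fitted).
#'
#' @param msdCurve an [MsdCurve-class] with at least two lags.
#' @return an [MsdFit-class].
#' @export
fitMsdLinear <- function(msdCurve) {
  if (length(msdCurve@lags) < 2L)
    stop("at least two lags are required for the linear MSD fit")
  fit <- stats::lm(msd ~ lags,
                   data = data.frame(lags = msdCurve@lags,
                                     msd = msdCurve@msd))
  sst <- sum((msdCurve@msd - mean(msdCurve@msd))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  new("MsdFit", D = unname(stats::coef(fit)[2]) / 4,
      intercept = unname(stats::coef(fit)[1]), rSquared = r2)
}

# model CDF of the squared-displacement mixture:
# F(u) = 1 - sum_i f_i exp(-u / (4 D_i dt))
sqdMixtureCdf <- function(u, D, f, dt) {
  1 - rowSums(vapply(seq_along(D),
                     function(i) f[i] * exp(-u / (4 * D[i] * dt)),
                     numeric(length(u))))
}

softmaxFractions <- function(logits) {
  e <- exp(c(logits, 0) - max(logits, 0))
  e / sum(e)
}

# evaluation grid for a condition's empirical CDF: the full sorted
# sample for small n, otherwise nGrid points log-spaced over the
# sample range. Log spacing gives the upper tail -- where a small
# fast-mobile population lives -- enough support points that the
# least squares can resolve percent-level fractions.
ecdfGrid <- function(x, nGrid) {
  n <- length(x)
  if (n <= nGrid) {
    xs <- sort(x)
    return(list(u = xs, F = seq_len(n) / n))
  }
  lo <- max(stats::quantile(x, 0.001), min(x[x > 0]), 1e-12)
  u <- exp(seq(log(lo), log(max(x)), length.out = nGrid))
  list(u = u, F = stats::ecdf(x)(u))
}

# EM for a k-component exponential mixture with means shared across
# conditions and per-condition weights; used to seed the CDF least
# squares with a start that resolves small populations.
emExponentialMixture <- function(data, k, m0, maxIter = 300L,
                                 tol = 1e-9) {
  nc <- length(data)
  m <- m0
  f <- matrix(1 / k, nrow = nc, ncol = k)
  for (it in seq_len(maxIter)) {
    num <- 0
    den <- 0
    fNew <- f
    for (ci in seq_len(nc)) {
      x <- data[[ci]]
      lw <- vapply(seq_len(k), function(i)
        log(pmax(f[ci, i], 1e-300)) - log(m[i]) - x / m[i],
        numeric(length(x)))
      mx <- do.call(pmax, lapply(seq_len(k), function(i) lw[, i]))
      r <- exp(lw - mx)
      r <- r / rowSums(r)
      fNew[ci, ] <- colMeans(r)
      num <- num + colSums(r * x)
      den <- den + colSums(r)
    }
    mNew <- num / pmax(den, 1e-300)
    if (max(abs(mNew - m) / pmax(m, 1e-12)) < tol &&
        max(abs(fNew - f)) < tol) {
      m <- mNew
      f <- fNew
      break
    }
    m <- mNew
    f <- fNew
  }
  list(m = m, f = f)
}

#' Global multi-state squared-displacement mixture fit
#'
#' Fits the cumulative distribution of squared frame-to-frame
#' displacements to a mixture of up to three diffusive states,
#' `F(u) = 1 - sum_i f_i exp(-u / (4 D_i dt))`, by least squares on
#' the empirical CDF. The diffusion constants `D_i` are shared across
#' all supplied conditions while the fractions `f_i` are free per
#' condition, which makes the population fractions directly comparable
#' between conditions. Optimization is multi-start (diffusion starts
#' log-spaced over 1e-4..10 um^2/s plus a quantile-based start);
#' standard errors come from a nonparametric bootstrap over steps.
#'
#' @param sqdByCondition named list of numeric vectors of squared
#'   displacements (um^2), one per condition; a single numeric vector
#'   or the `data.frame` returned by [squaredDisplacements()] is also
#'   accepted.
#' @param nComponents number of diffusive states (1..3).
#' @param frameInterval frame interval, s.
#' @param nStarts number of multi-start optimizations.
#' @param nGrid maximum number of empirical-CDF evaluation points per
#'   condition.
#' @param minSteps required minimum number of steps per condition.
#' @param nBoot bootstrap replicates for standard errors (0 disables).
#' @param seed RNG seed for starts and bootstrap.
#' @return a [DiffusionMixture-class] with components sorted by
#'   ascending D (confined < slow < fast).
#' @examples
#' sqd <- simulateSquaredDisplacements(c(0.7, 0.3), c(0.01, 0.2),
#'                                     0.024, 5000, seed = 2)
#' fitSqdMixtureGlobal(list(wt = sqd), nComponents = 2,
#'                     frameInterval = 0.024)
#' @export
fitSqdMixtureGlobal <- function(sqdByCondition, nComponents = 3L,
                                frameInterval, nStarts = 6L, nGrid = 800L,
                                minSteps = 200L, nBoot = 0L, seed = 1L) {
  if (is.data.frame(sqdByCondition))
    sqdByCondition <- split(sqdByCondition$sqd, sqdByCondition$condition)
  if (is.numeric(sqdByCondition))
    sqdByCondition <- list(condition = sqdByCondition)
  k <- as.integer(nComponents)
  if (k < 1L || k > 3L) stop("nComponents must be 1, 2 or 3")
  if (frameInterval <= 0) stop("frameInterval must be positive")
  nc <- length(sqdByCondition)
  if (is.null(names(sqdByCondition)))
    names(sqdByCondition) <- paste0("condition", seq_len(nc))
  ns <- vapply(sqdByCondition, length, integer(1))
  if (any(ns < minSteps))
    stop(sprintf("each condition needs >= %d squared displacements", minSteps))

  logitsFromFractions <- function(f) {
    f <- pmin(pmax(f, 1e-8), 1 - 1e-8)
    log(f[-k] / f[k])
  }

  fitOnce <- function(data, starts) {
    grids <- lapply(data, ecdfGrid, nGrid = nGrid)
    obj <- function(par) {
      D <- exp(par[seq_len(k)])
      tot <- 0
      for (ci in seq_len(nc)) {
        f <- if (k > 1)
          softmaxFractions(par[k + (ci - 1L) * (k - 1L) + seq_len(k - 1L)])
        else 1
        g <- grids[[ci]]
        tot <- tot + mean((sqdMixtureCdf(g$u, D, f, frameInterval) - g$F)^2)
      }
      tot
    }
    best <- NULL
    for (st in starts) {
      logits <- if (k == 1L) numeric(0)
        else if (is.null(st$fractions)) rep(0, nc * (k - 1L))
        else as.vector(t(apply(st$fractions, 1, logitsFromFractions)))
      par0 <- c(log(st$D), logits)
      opt <- if (length(par0) == 1L)
        try(stats::optim(par0, obj, method = "Brent", lower = log(1e-8),
                         upper = log(100)), silent = TRUE)
      else
        try(stats::optim(par0, obj, method = "Nelder-Mead",
                         control = list(maxit = 1000,
                                        reltol = 1e-10)), silent = TRUE)
      if (inherits(opt, "try-error")) next
      if (length(par0) > 1L) {
        opt2 <- try(stats::optim(opt$par, obj, method = "BFGS",
                                 control = list(maxit = 500,
                                                reltol = 1e-12)),
                    silent = TRUE)
        if (!inherits(opt2, "try-error")) opt <- opt2
      }
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (is.null(best))
      stop("squared-displacement mixture fit did not converge from any start")
    D <- exp(best$par[seq_len(k)])
    fr <- matrix(1, nrow = nc, ncol = k)
    if (k > 1)
      for (ci in seq_len(nc))
        fr[ci, ] <- softmaxFractions(
          best$par[k + (ci - 1L) * (k - 1L) + seq_len(k - 1L)])
    ord <- order(D, -colMeans(fr))  # ascending D; ties by larger fraction
    list(D = D[ord], fractions = fr[, ord, drop = FALSE], par = best$par,
         value = best$value)
  }

  set.seed(as.integer(seed))
  pooled <- unlist(sqdByCondition, use.names = FALSE)
  qStart <- sort(pmax(
    stats::quantile(pooled, probs = seq(0.25, 0.95,
                                        length.out = k)) / (4 * frameInterval),
    1e-5))
  em <- emExponentialMixture(sqdByCondition, k,
                             m0 = unname(qStart) * 4 * frameInterval)
  emStart <- list(D = pmax(em$m / (4 * frameInterval), 1e-8),
                  fractions = em$f)
  starts <- c(list(emStart, list(D = unname(qStart))),
              replicate(max(nStarts - 2L, 0L),
                        list(D = sort(exp(stats::runif(k, log(1e-4),
                                                       log(10))))),
                        simplify = FALSE))
  fit <- fitOnce(sqdByCondition, starts)

  # near-identical diffusion constants cannot be distinguished: merge
  if (k > 1) {
    rel <- diff(log(fit$D))
    if (any(rel < 0.01)) {
      warning("two diffusion constants collapsed; reducing component count")
      keep <- c(TRUE, rel >= 0.01)
      Dm <- fit$D[keep]
      grp <- cumsum(keep)
      fm <- t(apply(fit$fractions, 1, function(f) tapply(f, grp, sum)))
      fm <- matrix(fm, nrow = nc)
      fit <- list(D = Dm, fractions = fm, par = fit$par)
      k <- length(Dm)
    }
  }

  seD <- rep(NA_real_, k)
  seF <- matrix(NA_real_, nrow = nc, ncol = k)
  if (nBoot > 0L) {
    bD <- matrix(NA_real_, nrow = nBoot, ncol = k)
    bF <- array(NA_real_, dim = c(nBoot, nc, k))
    for (b in seq_len(nBoot)) {
      res <- lapply(sqdByCondition,
                    function(x) x[sample.int(length(x), replace = TRUE)])
      fb <- try(fitOnce(res, list(list(D = fit$D,
                                       fractions = fit$fractions))),
                silent = TRUE)
      if (inherits(fb, "try-error") || length(fb$D) != k) next
      bD[b, ] <- fb$D
      bF[b, , ] <- fb$fractions
    }
    seD <- apply(bD, 2, stats::sd, na.rm = TRUE)
    seF <- apply(bF, c(2, 3), stats::sd, na.rm = TRUE)
  }

  fr <- fit$fractions
  rownames(fr) <- names(sqdByCondition)
  colnames(fr) <- componentLabels(k)
  new("DiffusionMixture", D = fit$D, fractions = fr, seD = seD,
      seFractions = seF, nSteps = stats::setNames(as.numeric(ns),
                                                  names(sqdByCondition)),
      frameInterval = frameInterval)
}

#' Classify tracks by mobility state
#'
#' Assigns each track the mixture component maximizing the likelihood
#' of its squared frame-to-frame displacements (each exponential with
#' mean `4 D_i dt`, weighted by the condition's fitted fraction).
#' Labels follow ascending D: confined, slow, fast. Tracks with fewer
#' than two localizations (no displacement) remain unlabelled.
#'
#' @param ts a [TrackSet-class].
#' @param mixture a fitted [DiffusionMixture-class].
#' @return the [TrackSet-class] with a `label` column added.
#' @export
classifyTracks <- function(ts, mixture) {
  tr <- ts@tracks
  if (!nrow(tr)) return(ts)
  D <- mixture@D
  fr <- mixture@fractions
  ci <- match(ts@condition, rownames(fr))
  if (is.na(ci)) ci <- 1L
  f <- pmax(fr[ci, ], 1e-12)
  m <- pmax(4 * D * ts@frameInterval, 1e-12)
  lbl <- componentLabels(length(D))

  perTrack <- vapply(split(tr[c("frame", "x", "y")], tr$track_id),
                     function(d) {
    if (nrow(d) < 2L) return(NA_character_)
    # classification uses every consecutive-frame step, including the
    # final one (no terminal-pair exclusion: more data, no fit involved)
    end <- match(d$frame + 1L, d$frame)
    ok <- !is.na(end)
    if (!any(ok)) return(NA_character_)
    s <- (d$x[end[ok]] - d$x[which(ok)])^2 + (d$y[end[ok]] - d$y[which(ok)])^2
    ll <- vapply(seq_along(D), function(i)
      log(f[i]) + sum(stats::dexp(s, rate = 1 / m[i], log = TRUE)),
      numeric(1))
    lbl[which.max(ll)]
  }, character(1))

  tr$label <- perTrack[match(as.character(tr$track_id),
                             names(perTrack))]
  out <- ts
  out@tracks <- tr
  out
}
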