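#' Construct a cell geometry
#'
#' @param shape `"rod"` (2D spherocylinder, the TIRF projection of a
#'   rod-shaped cell) or `"sphere"` (disc; protoplasts and L-forms).
#' @param length cap-to-cap long-axis extent, um. For spheres this
#'   defaults to `width`.
#' @param width cell diameter, um.
#' @return a [CellGeometry-class].
#' @examples
#' cellGeometry("rod", length = 3, width = 1)
#' cellGeometry("sphere", width = 2)
#' @export
cellGeometry <- function(shape = c("rod", "sphere"), length = NULL,
                         width = 1) {
  shape <- match.arg(shape)
  if (shape == "sphere") length <- width
  if (is.null(length))
    stop("length is required for rod geometries")
  new("CellGeometry", shape = shape, length = as.numeric(length),
      width = as.numeric(width))
}

# Signed distance to the cell outline (< 0 inside). Both shapes are
# capsules: for a sphere the core segment degenerates to a point.
geometrySdf <- function(geometry, x, y) {
  a <- max((geometry@length - geometry@width) / 2, 0)
  r <- geometry@width / 2
  cx <- pmin(pmax(x, -a), a)
  sqrt((x - cx)^2 + y^2) - r
}

#' Test whether points lie inside a geometry
#'
#' @param geometry a [CellGeometry-class].
#' @param x,y coordinates in um (cell centred at the origin, long axis
#'   along x).
#' @param tol boundary tolerance in um.
#' @return logical vector.
#' @export
insideGeometry <- function(geometry, x, y, tol = 1e-9) {
  geometrySdf(geometry, x, y) <= tol
}

#' Sample points uniformly inside a geometry
#'
#' Rejection sampling from the bounding box.
#'
#' @param geometry a [CellGeometry-class].
#' @param n number of points.
#' @return `data.frame` with columns `x`, `y` (um).
#' @export
samplePointsInGeometry <- function(geometry, n) {
  hx <- geometry@length / 2
  hy <- geometry@width / 2
  out <- matrix(NA_real_, nrow = 0, ncol = 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    px <- stats::runif(m, -hx, hx)
    py <- stats::runif(m, -hy, hy)
    keep <- insideGeometry(geometry, px, py)
    out <- rbind(out, cbind(px[keep], py[keep]))
  }
  out <- out[seq_len(n), , drop = FALSE]
  data.frame(x = out[, 1], y = out[, 2])
}

# Specular reflection of points back into the geometry: mirror across
# the nearest boundary point, iterating for steps that overshoot past
# the far wall. Falls back to projection onto the boundary if a point
# is still outside after maxIter mirrors (only reachable for steps many
# cell widths long).
reflectIntoGeometry <- function(geometry, x, y, maxIter = 25L) {
  a <- max((geometry@length - geometry@width) / 2, 0)
  r <- geometry@width / 2
  for (i in seq_len(maxIter)) {
    cx <- pmin(pmax(x, -a), a)
    dx <- x - cx
    dist <- sqrt(dx^2 + y^2)
    out <- dist > r
    if (!any(out)) break
    sc <- (2 * r - dist[out]) / dist[out]
    x[out] <- cx[out] + dx[out] * sc
    y[out] <- y[out] * sc
  }
  still <- geometrySdf(geometry, x, y) > 0
  if (any(still)) {
    cx <- pmin(pmax(x[still], -a), a)
    dx <- x[still] - cx
    dist <- sqrt(dx^2 + y[still]^2)
    sc <- (r * (1 - 1e-9)) / dist
    x[still] <- cx + dx * sc
    y[still] <- y[still] * sc
  }
  cbind(x = x, y = y)
}
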