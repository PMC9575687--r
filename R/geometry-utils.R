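#' @include AllClasses.R
NULL

## ---- quaternions -----------------------------------------------------------

#' Convert a unit quaternion (w, x, y, z) to a 3x3 rotation matrix
#' @param q numeric(4) unit quaternion.
#' @return 3x3 rotation matrix.
#' @keywords internal
quatToMatrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Axis-angle rotation matrix (Rodrigues)
#' @param axis numeric(3) rotation axis (normalized internally).
#' @param thetaDeg rotation angle in degrees.
#' @keywords internal
axisAngleMatrix <- function(axis, thetaDeg) {
  u <- axis / sqrt(sum(axis^2))
  th <- thetaDeg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * tcrossprod(u)
}

quatFromAxisAngle <- function(axis, thetaDeg) {
  u <- axis / sqrt(sum(axis^2))
  th <- thetaDeg * pi / 180 / 2
  c(cos(th), sin(th) * u)
}

quatMultiply <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] +
      c(a[3] * b[4] - a[4] * b[3],
        a[4] * b[2] - a[2] * b[4],
        a[2] * b[3] - a[3] * b[2]))
}

## ---- deterministic sub-seeds ----------------------------------------------

#' Derive a reproducible 31-bit sub-seed from a master seed
#' @param seed integer master seed.
#' @param k integer stream index.
#' @keywords internal
deriveSeed <- function(seed, k) {
  ## Weyl-style mixing kept inside 2^31-1 using double arithmetic
  s <- (as.numeric(seed) * 2654435.0 + as.numeric(k) * 40503.0 + 977.0)
  as.integer(s %% 2147483629)
}

## ---- projection-direction grid --------------------------------------------

#' Deterministic Fibonacci-sphere projection directions
#'
#' Samples `nPD` approximately uniform directions on the upper hemisphere of
#' the unit sphere and returns, for each, the quaternion rotating that
#' viewing direction onto +z (so projecting the rotated model along +z views
#' the model from the sampled direction).
#'
#' @param nPD integer number of projection directions.
#' @param apertureDeg angular aperture width assigned to each PD (degrees).
#' @return a [ProjectionDirections-class] object.
#' @export
fibonacciPDs <- function(nPD, apertureDeg = 3) {
  stopifnot(nPD >= 1)
  i <- seq_len(nPD) - 0.5
  phi <- (1 + sqrt(5)) / 2
  ## upper hemisphere: z from ~1 down to ~0
  z <- 1 - i / nPD
  r <- sqrt(pmax(0, 1 - z^2))
  az <- 2 * pi * i / phi
  v <- cbind(r * cos(az), r * sin(az), z)
  quats <- t(apply(v, 1, function(dir) {
    ## rotation taking dir -> +z: rotate about axis = dir x z
    zax <- c(0, 0, 1)
    cr <- c(dir[2] * zax[3] - dir[3] * zax[2],
            dir[3] * zax[1] - dir[1] * zax[3],
            dir[1] * zax[2] - dir[2] * zax[1])
    s <- sqrt(sum(cr^2))
    if (s < 1e-12) return(c(1, 0, 0, 0))
    ang <- atan2(s, sum(dir * zax)) * 180 / pi
    quatFromAxisAngle(cr, ang)
  }))
  new("ProjectionDirections", id = seq_len(nPD), quaternion = quats,
      apertureDeg = apertureDeg)
}

#' @describeIn fibonacciPDs subset a set of projection directions.
#' @param x a ProjectionDirections object.
#' @param i index vector.
#' @export
setMethod("[", "ProjectionDirections", function(x, i) {
  new("ProjectionDirections", id = x@id[i],
      quaternion = x@quaternion[i, , drop = FALSE],
      apertureDeg = x@apertureDeg)
})

## ---- polygon primitives ----------------------------------------------------

#' Signed area of a simple polygon (shoelace); positive if counterclockwise
#' @param poly two-column matrix of vertices (not closed).
#' @export
polygonArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Vectorized point-in-polygon (even-odd ray casting)
#'
#' Boundary points count as inside.
#' @param pts two-column matrix of query points.
#' @param poly two-column polygon matrix.
#' @return logical vector.
#' @keywords internal
pointInPolygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  px <- pts[, 1]; py <- pts[, 2]
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  onEdge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    ## edge membership (collinear and within bounding box)
    cr <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    onSeg <- abs(cr) < 1e-12 * (abs(xj - xi) + abs(yj - yi) + 1) &
      px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
      py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12
    onEdge <- onEdge | onSeg
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onEdge
}

#' Clip a polygon with the half-plane {p : dot(nrm, p) <= off}
#' (Sutherland-Hodgman, one clip edge)
#' @keywords internal
clipHalfPlane <- function(poly, nrm, off) {
  n <- nrow(poly)
  out <- matrix(numeric(0), ncol = 2)
  d <- poly %*% nrm - off
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) out <- rbind(out, poly[i, ])
    if ((di < 0) != (dj < 0) && di != dj) {
      t <- di / (di - dj)
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  if (nrow(out) >= 3) out else matrix(numeric(0), ncol = 2)
}

#' Euclidean distance from points to a polygon boundary
#' @keywords internal
pointPolygonDistance <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  n <- nrow(poly)
  dmin <- rep(Inf, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    a <- poly[j, ]; b <- poly[i, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, nrow(pts)) else
      pmin(1, pmax(0, ((pts[, 1] - a[1]) * ab[1] +
                       (pts[, 2] - a[2]) * ab[2]) / len2))
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    dmin <- pmin(dmin, sqrt(dx * dx + dy * dy))
    j <- i
  }
  dmin
}

## ---- 2D histogram ----------------------------------------------------------

#' Count nonzero bins of the 2D histogram of a point set
#'
#' The bounding box is supplied by the caller so counts are comparable
#' across rotations of the same data.
#' @param xy two-column matrix.
#' @param box list with xlim, ylim.
#' @param bins bins per axis.
#' @keywords internal
nonzeroBins2D <- function(xy, box, bins) {
  ix <- findInterval(xy[, 1], seq(box$xlim[1], box$xlim[2], length.out = bins + 1),
                     rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(xy[, 2], seq(box$ylim[1], box$ylim[2], length.out = bins + 1),
                     rightmost.closed = TRUE, all.inside = TRUE)
  keep <- xy[, 1] >= box$xlim[1] & xy[, 1] <= box$xlim[2] &
    xy[, 2] >= box$ylim[1] & xy[, 2] <= box$ylim[2]
  length(unique((ix[keep] - 1L) * bins + iy[keep]))
}
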