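#' @include AllClasses.R geometry-utils.R
NULL

## circumcenter and squared circumradius of triangle (a, b, c)
.circum <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-14) return(c(NA, NA, Inf))
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  c(ux, uy, (ux - a[1])^2 + (uy - a[2])^2)
}

#' Delaunay triangulation of a 2D point set (Bowyer-Watson)
#'
#' Incremental insertion with vectorized circumcircle tests; intended for
#' the point-cloud sizes met in subspace partitioning (hundreds to a few
#' thousand points).
#'
#' @param pts two-column coordinate matrix (duplicates removed).
#' @return list with `triangles` (m x 3 index matrix into `pts`) and
#'   `circumradius` (length m).
#' @export
delaunay <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 distinct points")
  ## super-triangle
  rng <- apply(pts, 2, range)
  ctr <- colMeans(rng)
  span <- max(rng[2, ] - rng[1, ]) * 50 + 1
  sup <- rbind(ctr + c(-span, -span), ctr + c(span, -span), ctr + c(0, span))
  P <- rbind(pts, sup)
  cap <- 4L * n + 16L
  tri <- matrix(0L, cap, 3)
  cc <- matrix(0, cap, 2)
  r2 <- numeric(cap)
  tri[1, ] <- c(n + 1L, n + 2L, n + 3L)
  ci <- .circum(sup[1, ], sup[2, ], sup[3, ])
  cc[1, ] <- ci[1:2]; r2[1] <- ci[3]
  m <- 1L
  alive <- rep(FALSE, cap); alive[1] <- TRUE
  for (p in seq_len(n)) {
    px <- P[p, 1]; py <- P[p, 2]
    idx <- which(alive[seq_len(m)])
    bad <- idx[(px - cc[idx, 1])^2 + (py - cc[idx, 2])^2 <= r2[idx] * (1 + 1e-12)]
    if (!length(bad)) next  # numerically degenerate; skip point
    ## boundary edges: edges of bad triangles appearing exactly once
    e <- rbind(tri[bad, c(1, 2), drop = FALSE],
               tri[bad, c(2, 3), drop = FALSE],
               tri[bad, c(3, 1), drop = FALSE])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    single <- e[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    alive[bad] <- FALSE
    for (q in seq_len(nrow(single))) {
      a <- single[q, 1]; b <- single[q, 2]
      ci <- .circum(P[a, ], P[b, ], P[p, ])
      if (!is.finite(ci[3])) next
      m <- m + 1L
      if (m > cap) {
        cap2 <- cap * 2L
        tri <- rbind(tri, matrix(0L, cap2 - cap, 3))
        cc <- rbind(cc, matrix(0, cap2 - cap, 2))
        r2 <- c(r2, numeric(cap2 - cap))
        alive <- c(alive, rep(FALSE, cap2 - cap))
        cap <- cap2
      }
      tri[m, ] <- c(a, b, p)
      cc[m, ] <- ci[1:2]; r2[m] <- ci[3]
      alive[m] <- TRUE
    }
  }
  keep <- which(alive[seq_len(m)])
  T <- tri[keep, , drop = FALSE]
  R <- sqrt(r2[keep])
  real <- rowSums(T > n) == 0L    # drop super-triangle incidences
  list(triangles = T[real, , drop = FALSE], circumradius = R[real],
       points = pts)
}

## boundary of a triangle subset: edges used exactly once, stitched into
## cycles; returns list of vertex-index cycles
.boundaryCycles <- function(T) {
  e <- rbind(T[, c(1, 2), drop = FALSE], T[, c(2, 3), drop = FALSE],
             T[, c(3, 1), drop = FALSE])
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  key <- paste(a, b)
  once <- key %in% names(which(table(key) == 1L))
  eb <- cbind(a[once], b[once])
  if (!nrow(eb)) return(list())
  adj <- split(c(eb[, 2], eb[, 1]), c(eb[, 1], eb[, 2]))
  used <- rep(FALSE, nrow(eb))
  ekey <- paste(eb[, 1], eb[, 2])
  cycles <- list()
  for (s in seq_len(nrow(eb))) {
    if (used[s]) next
    start <- eb[s, 1]
    cyc <- c(start)
    cur <- start; prev <- -1L
    repeat {
      nbrs <- adj[[as.character(cur)]]
      nxt <- NA_integer_
      for (cand in nbrs) {
        k <- paste(min(cur, cand), max(cur, cand))
        ei <- match(k, ekey)
        if (!is.na(ei) && !used[ei]) { nxt <- cand; used[ei] <- TRUE; break }
      }
      if (is.na(nxt)) break
      if (nxt == start) break
      cyc <- c(cyc, nxt)
      prev <- cur; cur <- nxt
    }
    if (length(cyc) >= 3) cycles <- c(cycles, list(cyc))
  }
  cycles
}

## number of edge-connected components of a triangle subset
.triComponents <- function(T) {
  m <- nrow(T)
  if (m == 0) return(0L)
  e <- rbind(cbind(T[, 1], T[, 2], seq_len(m)),
             cbind(T[, 2], T[, 3], seq_len(m)),
             cbind(T[, 3], T[, 1], seq_len(m)))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  byEdge <- split(e[, 3], key)
  parent <- seq_len(m)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (g in byEdge) if (length(g) == 2) {
    ra <- find(g[1]); rb <- find(g[2])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(m), find, integer(1))))
}

#' Alpha-shape polygon of a 2D point cloud
#'
#' Builds the Delaunay triangulation and keeps triangles whose
#' circumradius is at most `1/alpha`; `alpha = 0` keeps everything and
#' reduces to the convex hull. When `alpha` is NULL the largest alpha is
#' selected (bisection over the sorted circumradii) such that the kept
#' complex is a single edge-connected component with exactly one boundary
#' cycle (no holes) containing at least 99 percent of the points. If no
#' alpha achieves this, the convex hull is returned with a warning. Clouds
#' larger than `maxPoints` are thinned by a deterministic stride before
#' triangulation (containment is still checked on all points).
#'
#' @param points N x 2 matrix (N >= 10).
#' @param alpha fixed alpha (1/length units), or NULL to select.
#' @param maxPoints triangulation subsample cap.
#' @return two-column polygon matrix (counterclockwise, not closed) with
#'   attribute `alpha` (the value used; 0 means convex hull).
#' @export
alphaShapePolygon <- function(points, alpha = NULL, maxPoints = 1500L) {
  points <- unique(as.matrix(points))
  if (nrow(points) < 10) stop("need at least 10 points")
  tpts <- points
  if (nrow(tpts) > maxPoints) {
    keep <- unique(round(seq(1, nrow(tpts), length.out = maxPoints)))
    tpts <- tpts[keep, , drop = FALSE]
  }
  dt <- tryCatch(delaunay(tpts), error = function(e) NULL)
  hullPoly <- function() {
    h <- grDevices::chull(points)
    poly <- points[h, , drop = FALSE]
    if (polygonArea(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
    attr(poly, "alpha") <- 0
    poly
  }
  if (is.null(dt) || nrow(dt$triangles) == 0) {
    warning("triangulation failed; falling back to the convex hull")
    return(hullPoly())
  }
  polyFor <- function(rThr) {
    keep <- dt$circumradius <= rThr
    T <- dt$triangles[keep, , drop = FALSE]
    if (!nrow(T)) return(NULL)
    if (.triComponents(T) != 1L) return(NULL)
    cyc <- .boundaryCycles(T)
    if (length(cyc) != 1L) return(NULL)
    poly <- dt$points[cyc[[1]], , drop = FALSE]
    if (polygonArea(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
    if (mean(pointInPolygon(points, poly)) < 0.99) return(NULL)
    poly
  }
  rr <- sort(unique(dt$circumradius))
  if (!is.null(alpha)) {
    rThr <- if (alpha <= 0) Inf else 1 / alpha
    poly <- polyFor(rThr)
    if (is.null(poly)) {
      warning("point cloud fragments at the requested alpha; ",
              "falling back to the convex hull")
      return(hullPoly())
    }
    attr(poly, "alpha") <- alpha
    return(poly)
  }
  ## bisection on the sorted circumradius scale for the smallest radius
  ## threshold (largest alpha) that still yields a valid single polygon
  lo <- 1L; hi <- length(rr)
  if (is.null(polyFor(rr[hi]))) {
    warning("point cloud fragments at all alpha; ",
            "falling back to the convex hull")
    return(hullPoly())
  }
  while (hi - lo > 0L) {
    mid <- (lo + hi) %/% 2L
    if (!is.null(polyFor(rr[mid]))) hi <- mid else lo <- mid + 1L
  }
  poly <- polyFor(rr[hi])
  attr(poly, "alpha") <- 1 / rr[hi]
  poly
}
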