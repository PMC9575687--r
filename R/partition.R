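#' @include AllClasses.R alphashape.R realign.R
NULL

#' Inverse-cosine transform of a CM eigenvector
#'
#' Rescales the column to [-1, 1] (min-max by default, or a robust
#' quantile range) and applies arccos, mapping the nonuniform rates of
#' change of the sampled cosine eigenfunctions onto a uniform-rate
#' coordinate in [0, pi]. The map is monotone decreasing: the column
#' maximum maps to 0 and the minimum to pi.
#'
#' @param psi numeric eigenvector column (non-constant).
#' @param quantileRange optional c(lo, hi) probability pair; when supplied
#'   the rescaling range is taken from these quantiles instead of the
#'   min-max (values outside are clipped).
#' @return numeric vector of Phi values in [0, pi].
#' @export
arccosTransform <- function(psi, quantileRange = NULL) {
  r <- if (is.null(quantileRange)) range(psi) else
    stats::quantile(psi, quantileRange, names = FALSE)
  if (diff(r) < 1e-300) stop("constant eigenvector column")
  z <- (psi - r[1]) / (r[2] - r[1]) * 2 - 1
  acos(pmin(1, pmax(-1, z)))
}

## absolute-value fit Phi2 = a |Phi1 - h| + k; returns (a, h, k)
.absFit <- function(p1, p2) {
  sse <- function(h) {
    X <- cbind(abs(p1 - h), 1)
    f <- stats::lm.fit(X, p2)
    sum(f$residuals^2)
  }
  h <- stats::optimize(sse, range(p1))$minimum
  f <- stats::lm.fit(cbind(abs(p1 - h), 1), p2)
  c(a = f$coefficients[[1]], h = h, k = f$coefficients[[2]])
}

## count crossings of the ray anchor + t*dir (t > 0) with polygon edges,
## deduplicating hits at shared vertices
.rayCrossings <- function(anchor, dir, poly) {
  n <- nrow(poly)
  hits <- numeric(0)
  j <- n
  for (i in seq_len(n)) {
    a <- poly[j, ]; b <- poly[i, ]
    e <- b - a
    den <- dir[1] * (-e[2]) - dir[2] * (-e[1])
    if (abs(den) > 1e-14) {
      rhs <- a - anchor
      t <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / den
      u <- (dir[1] * rhs[2] - dir[2] * rhs[1]) / den
      if (t > 1e-9 && u >= -1e-9 && u <= 1 + 1e-9) hits <- c(hits, t)
    }
    j <- i
  }
  if (!length(hits)) return(0L)
  hits <- sort(hits)
  length(hits[c(TRUE, diff(hits) > 1e-9 * (1 + max(hits)))])
}

#' Place the ray-sweep anchor for a transformed CM subspace
#'
#' The arccos-transformed CM point cloud is V-shaped; a preliminary
#' absolute-value fit `Phi2 = a |Phi1 - h| + k` locates its symmetry axis
#' and apex. The anchor is placed on the symmetry axis on the apex side of
#' the cloud (opposite the arms' opening), offset from the vertex (h, k)
#' away from the cloud mass by `offsetFrac` times the cloud's bounding-box
#' height. The whole cloud then subtends less than a half-turn about the
#' anchor (every equal-area cut is a single half-plane clip and the swept
#' area is exactly monotone in the sweep angle); with the default distant
#' anchor the sweep rays are nearly parallel inside the cloud, so a
#' point's bin depends almost only on its position along the leading
#' (least-noisy) transformed coordinate rather than on the folded second
#' one. If the polygon subtends too much, the offset is doubled (up to
#' three times) before giving up.
#'
#' @param polygon alpha-shape polygon of the cloud.
#' @param points N x 2 matrix of transformed (Phi) coordinates.
#' @param offsetFrac anchor offset as a multiple of the bounding-box
#'   height.
#' @return numeric(2) anchor, with attributes `absFit` (a, h, k) and
#'   `offset` (the offset used).
#' @export
placeAnchor <- function(polygon, points, offsetFrac = 2) {
  fit <- .absFit(points[, 1], points[, 2])
  a <- fit[["a"]]; h <- fit[["h"]]; k <- fit[["k"]]
  bbh <- diff(range(points[, 2]))
  dirSign <- if (a >= 0) -1 else 1   # move away from the arms' opening
  off <- offsetFrac * bbh
  for (try in 0:3) {
    anchor <- c(h, k + dirSign * off)
    ## the anchor must lie outside the polygon and see it within less than
    ## a half-turn, so each equal-area cut is a single half-plane clip and
    ## the swept area is exactly monotone in the sweep angle
    ok <- !pointInPolygon(matrix(anchor, ncol = 2), polygon)
    if (ok) {
      ang <- atan2(polygon[, 2] - anchor[2], polygon[, 1] - anchor[1])
      ang <- sort(ang %% (2 * pi))
      gap <- max(diff(c(ang, ang[1] + 2 * pi)))
      ok <- gap > pi + 5 * pi / 180
    }
    if (ok) {
      attr(anchor, "absFit") <- fit
      attr(anchor, "offset") <- off
      return(anchor)
    }
    off <- off * 2
  }
  stop("no anchor position sees the whole polygon within a half-turn; ",
       "consider the general-conic partition fallback")
}

## rotate the frame so all polygon vertex angles about the anchor lie in
## (0, pi); returns the frame rotation angle
.sweepFrame <- function(polygon, anchor) {
  ang <- atan2(polygon[, 2] - anchor[2], polygon[, 1] - anchor[1])
  ang <- sort(ang %% (2 * pi))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  g <- which.max(gaps)
  if (gaps[g] <= pi)
    stop("polygon is not star-shaped about the anchor ",
         "(angular extent >= half turn); diagnostic angles attached")
  ## rotate so the gap maps onto (pi, 2 pi)
  gapStart <- ang[g] + gaps[g] / 2     # middle of the empty sector
  -(gapStart + pi / 2)                  # empty sector centered at 3 pi / 2
}

.rot2 <- function(xy, th) {
  cbind(cos(th) * xy[, 1] - sin(th) * xy[, 2],
        sin(th) * xy[, 1] + cos(th) * xy[, 2])
}

#' Partition a polygon into equal-area bins by an anchored ray sweep
#'
#' Rays from the anchor sweep monotonically across the polygon; cuts are
#' placed (bisection, 0.1 percent area tolerance) at sweep angles where
#' the cumulative swept area equals m/B of the polygon area. Because the
#' polygon subtends less than a half-turn about the anchor, each cut is a
#' half-plane clip through the anchor and the swept area is exactly
#' monotone in the sweep angle. Sub-polygons are returned contiguous and
#' ordered along increasing first coordinate of the cloud.
#'
#' @param polygon two-column polygon matrix.
#' @param anchor numeric(2) from [placeAnchor].
#' @param B number of bins (>= 2).
#' @return list with `subPolygons` (list of B polygons), `cutAngles`
#'   (B - 1 interior cut angles, radians, in the rotated sweep frame),
#'   `frameRotation`, and `areas`.
#' @export
equalAreaBins <- function(polygon, anchor, B) {
  B <- as.integer(B)
  if (B < 2) stop("B must be >= 2")
  th0 <- .sweepFrame(polygon, anchor)
  polyR <- .rot2(sweep(polygon, 2, anchor), th0)
  total <- abs(polygonArea(polyR))
  ## swept area at cut angle t: part of the polygon with vertex angle >= t
  sweptFrom <- function(t) {
    nrm <- c(-sin(t), cos(t))            # dot >= 0 <=> angle in (t, t+pi)
    piece <- clipHalfPlane(polyR, -nrm, 0)
    if (nrow(piece) < 3) 0 else abs(polygonArea(piece))
  }
  cuts <- numeric(B - 1)
  for (m in seq_len(B - 1)) {
    target <- total * m / B
    lo <- 0; hi <- pi
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (sweptFrom(mid) >= target) lo <- mid else hi <- mid
      if (abs(sweptFrom((lo + hi) / 2) - target) < 1e-3 * total / B &&
          hi - lo < 1e-9) break
    }
    cuts[m] <- (lo + hi) / 2
  }
  bounds <- c(pi, cuts, 0)
  subs <- vector("list", B)
  for (b in seq_len(B)) {
    hi <- bounds[b]; lo <- bounds[b + 1]
    piece <- polyR
    if (hi < pi) {  # keep angle <= hi
      nrm <- c(-sin(hi), cos(hi))
      piece <- clipHalfPlane(piece, nrm, 0)
    }
    if (lo > 0 && nrow(piece) >= 3) {  # keep angle >= lo
      nrm <- c(-sin(lo), cos(lo))
      piece <- clipHalfPlane(piece, -nrm, 0)
    }
    if (nrow(piece) < 3)
      stop("degenerate sub-polygon at bin ", b,
           "; polygon may not be star-shaped about the anchor")
    ## back to the original frame
    subs[[b]] <- sweep(.rot2(piece, -th0), 2, anchor, "+")
  }
  areas <- vapply(subs, function(p) abs(polygonArea(p)), numeric(1))
  if (max(abs(areas - total / B)) > 0.01 * total / B)
    warning("equal-area tolerance exceeded: max relative deviation ",
            signif(max(abs(areas - total / B)) / (total / B), 3))
  ## order bins along increasing Phi1 of their centroids
  cx <- vapply(subs, function(p) mean(p[, 1]), numeric(1))
  if (cx[1] > cx[B]) {
    subs <- rev(subs)
    cuts <- rev(cuts)
    attr(cuts, "reversed") <- TRUE
  }
  list(subPolygons = subs, cutAngles = cuts, frameRotation = th0,
       areas = areas, anchor = anchor)
}

#' Assign points to equal-area bins
#'
#' Points inside the alpha polygon are assigned by their sweep angle about
#' the anchor (boundary angles go to the lower-index bin); points outside
#' the polygon are assigned to the nearest sub-polygon by boundary
#' distance and flagged.
#'
#' @param points N x 2 matrix of transformed coordinates.
#' @param bins result of [equalAreaBins].
#' @param alphaPolygon the enclosing polygon.
#' @return a [BinSet-class].
#' @export
assignBins <- function(points, bins, alphaPolygon) {
  B <- length(bins$subPolygons)
  ptsR <- .rot2(sweep(points, 2, bins$anchor), bins$frameRotation)
  ang <- atan2(ptsR[, 2], ptsR[, 1])
  reversed <- isTRUE(attr(bins$cutAngles, "reversed"))
  cuts <- if (reversed) rev(bins$cutAngles) else bins$cutAngles
  ## sweep bins: bin 1 has angle in [cuts[1], pi], bin B angle in [0, cuts[B-1]]
  ## boundary angle == cut belongs to the lower-index bin
  binSweep <- findInterval(-ang, -c(pi, cuts), rightmost.closed = FALSE,
                           left.open = TRUE)
  binSweep[ang >= pi] <- 1L
  binSweep <- pmin(pmax(binSweep, 1L), B)
  bin <- if (reversed) B + 1L - binSweep else binSweep
  inside <- pointInPolygon(points, alphaPolygon)
  if (any(!inside)) {
    outPts <- points[!inside, , drop = FALSE]
    dmat <- vapply(bins$subPolygons, function(p)
      pointPolygonDistance(outPts, p), numeric(nrow(outPts)))
    dmat <- matrix(dmat, nrow = nrow(outPts))
    bin[!inside] <- max.col(-dmat, ties.method = "first")
  }
  occ <- tabulate(bin, nbins = B)
  new("BinSet", B = B, subPolygons = bins$subPolygons,
      binOfImage = as.integer(bin), occupancy = as.numeric(occ),
      alphaPolygon = as.matrix(alphaPolygon),
      anchor = as.numeric(bins$anchor), outside = !inside,
      cutAngles = as.numeric(bins$cutAngles))
}

#' Partition one CM subspace of an embedding into conformational bins
#'
#' Convenience wrapper chaining [arccosTransform] on both eigenvectors of
#' the CM subspace, [alphaShapePolygon], [placeAnchor], [equalAreaBins]
#' and [assignBins].
#'
#' @param emb a realigned [Embedding-class].
#' @param subspace integer(2) CM subspace indices.
#' @param B number of bins.
#' @param quantileRange passed to [arccosTransform]; the default trims a
#'   symmetric 2 percent before rescaling, making the transform robust to
#'   the unbounded extremes of noisy eigenvector coordinates (for
#'   noiseless data the trim is a no-op up to rounding).
#' @param maxPoints passed to [alphaShapePolygon].
#' @param offsetFrac passed to [placeAnchor].
#' @return a [BinSet-class]; the transformed coordinates are attached as
#'   attribute `phi`.
#' @export
partitionSubspace <- function(emb, subspace, B = 20L,
                              quantileRange = c(0.02, 0.98),
                              maxPoints = 1500L, offsetFrac = 2) {
  V <- eigVectors(emb)
  phi <- cbind(arccosTransform(V[, subspace[1]], quantileRange),
               arccosTransform(V[, subspace[2]], quantileRange))
  poly <- alphaShapePolygon(phi, maxPoints = maxPoints)
  ## nearly one-dimensional clouds (noiseless data): the alpha shape of an
  ## exact curve degenerates (on-curve slivers have unbounded
  ## circumradius), so thicken the cloud into a constant-width tube; equal
  ## area along the tube is then equal arc length, which is what the
  ## uniform-rate Phi coordinate calls for
  diagLen <- sqrt(sum(apply(phi, 2, function(z) diff(range(z)))^2))
  if (stats::median(pointPolygonDistance(phi, poly)) < 0.03 * diagLen) {
    rho <- 0.025 * diagLen
    ring <- cbind(cos(2 * pi * (0:11) / 12), sin(2 * pi * (0:11) / 12)) * rho
    aug <- do.call(rbind, lapply(seq_len(12), function(q)
      sweep(phi, 2, -ring[q, ])))
    poly <- alphaShapePolygon(rbind(phi, aug), maxPoints = 4L * maxPoints)
  }
  anchor <- placeAnchor(poly, phi, offsetFrac = offsetFrac)
  bins <- equalAreaBins(poly, anchor, B)
  bs <- assignBins(phi, bins, poly)
  attr(bs, "phi") <- phi
  bs
}

#' Average the raw images of each bin into a 2D movie
#'
#' Frame b is the pixel mean of exactly the images assigned to bin b; raw
#' images are untouched. Empty bins yield zero frames and are flagged.
#'
#' @param stack the source [ImageStack-class].
#' @param binOfImage integer bin per image (NA = unassigned) or a
#'   [BinSet-class].
#' @param B number of bins.
#' @param cmId,pdId,sense labels stored in the movie.
#' @return a [Movie2D-class].
#' @export
makeMovie <- function(stack, binOfImage, B, cmId = 1L, pdId = 1L,
                      sense = 1L) {
  if (is(binOfImage, "BinSet")) {
    B <- binOfImage@B
    binOfImage <- binOfImage@binOfImage
  }
  P <- dim(stack@images)[1]
  frames <- array(0, c(P, P, B))
  empty <- logical(B)
  for (b in seq_len(B)) {
    sel <- which(binOfImage == b)
    if (!length(sel)) { empty[b] <- TRUE; next }
    frames[, , b] <- rowMeans(stack@images[, , sel, drop = FALSE], dims = 2)
  }
  if (any(empty)) warning("empty bin(s): ", paste(which(empty), collapse = ", "))
  new("Movie2D", frames = frames, cmId = as.integer(cmId),
      pdId = as.integer(pdId), sense = as.integer(sense), empty = empty)
}

#' SVD noise-filtering of a 2D movie
#'
#' Frames are unrolled to a B x P^2 matrix, the top-k singular triplets
#' are kept, and the rank-k reconstruction is reshaped back.
#'
#' @param movie a [Movie2D-class].
#' @param k rank to keep (k <= min(B, P^2)).
#' @return filtered [Movie2D-class].
#' @export
svdFilterMovie <- function(movie, k) {
  d <- dim(movie@frames)
  B <- d[3]
  if (k > min(B, d[1] * d[2])) stop("k must be <= min(B, P^2)")
  M <- t(matrix(movie@frames, d[1] * d[2], B))
  sv <- svd(M, nu = k, nv = k)
  Mk <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
  initialize(movie, frames = array(t(Mk), d))
}
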