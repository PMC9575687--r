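#' @include AllClasses.R conic.R embedding.R
NULL

#' Number of planar rotation sub-matrices of a d-dimensional rotation
#'
#' A general d-dimensional rotation factors into d(d-1)/2 planar
#' (Givens-type) sub-rotations, one per eigenvector index pair.
#'
#' @param d embedding dimensionality (>= 2).
#' @return integer d(d-1)/2.
#' @examples
#' countRotationSubmatrices(5)  # 10
#' @export
countRotationSubmatrices <- function(d) {
  d <- as.integer(d)
  if (is.na(d) || d < 2) stop("d must be an integer >= 2")
  (d * (d - 1L)) %/% 2L
}

#' Fit all 2D eigenvector subspaces and identify the CM subspaces
#'
#' Scans every pair (i, j), i < j, of the leading eigenvectors, fits a
#' parabola (or general conic) to the scatter, and accepts CM subspaces
#' greedily by descending fit quality subject to two exclusion rules:
#' (i) harmonic exclusion -- a candidate sharing an eigenvector index with
#' an accepted CM subspace cannot be another CM (such subspaces are
#' recorded as harmonics); and (ii) functional dependence -- a candidate
#' one of whose eigenvectors is (up to polynomial warping) a function of
#' an accepted CM's eigenvector traces the same conformational coordinate
#' again, i.e. is a higher-order parabola of an already-found motion (e.g.
#' the cos(3 pi x)/cos(6 pi x) pair of a one-dimensional continuum, which
#' is index-disjoint from {Psi_1 x Psi_2} yet repeats the motion); such
#' candidates are recorded separately as rejected. Dependence is measured
#' as the R^2 of a degree-6 polynomial regression between the columns
#' (a genuine second CM fills a sheet against the first CM's
#' eigenvectors, giving near-zero dependence). Ties in fit quality are
#' broken lexicographically on (i, j). Localized eigenvectors --
#' kernel-noise spikes concentrated on a few points, recognized by a
#' participation ratio below max(8, N/20) -- are never CM candidates,
#' since a handful of points trivially fits a tight parabola.
#'
#' @param emb an [Embedding-class] with at least 4 eigenvectors.
#' @param nMax maximum number of CMs to accept.
#' @param r2Min minimum fit R^2 for acceptance (default 0.7).
#' @param constraint conic mode passed to [fitConic] ("parabola" for clean
#'   and noisy data, "general" for CTF-modified data).
#' @param depMax functional-dependence R^2 above which an index-disjoint
#'   candidate is rejected as a repeat of an accepted motion.
#' @return a [CMCatalog-class]; empty (with a message) when no subspace
#'   reaches `r2Min`, which indicates a featureless "globular" embedding.
#' @export
determineCMSubspaces <- function(emb, nMax = 3L, r2Min = 0.7,
                                 constraint = "parabola", depMax = 0.8) {
  V <- eigVectors(emb)
  d <- ncol(V)
  if (d < 4) stop("embedding must retain at least 4 eigenvectors")
  pairs <- which(upper.tri(matrix(0, d, d)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  fits <- vector("list", nrow(pairs))
  r2 <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    f <- fitConic(V[, pairs[k, ], drop = FALSE], constraint)
    f@subspace <- as.integer(pairs[k, ])
    fits[[k]] <- f
    r2[k] <- f@r2
  }
  ## R^2 of a degree-6 polynomial regression of v on u (is v a warped
  ## function of u, as harmonics of one coordinate are of each other?)
  polyDep <- function(u, v) {
    X <- try(stats::poly(u, degree = 6), silent = TRUE)
    if (inherits(X, "try-error")) return(1)  # degenerate u: treat as dependent
    f <- stats::lm.fit(cbind(1, X), v)
    sst <- sum((v - mean(v))^2)
    if (sst < 1e-300) 1 else 1 - sum(f$residuals^2) / sst
  }
  ## localized eigenvectors (noise spikes concentrated on a few points)
  ## trivially fit tight parabolas; they are never CM candidates
  pr <- 1 / colSums(sweep(V, 2, sqrt(colSums(V^2)), "/")^4)
  prMin <- max(8, nrow(V) / 20)
  ord <- order(-round(r2, 9), pairs[, 1], pairs[, 2])
  cms <- list(); harmonics <- list(); rejected <- list()
  usedIdx <- integer()
  for (k in ord) {
    if (r2[k] < r2Min) break
    ij <- as.integer(pairs[k, ])
    if (any(pr[ij] < prMin)) next
    if (length(cms) >= nMax) {
      if (any(ij %in% usedIdx)) harmonics <- c(harmonics, list(ij))
      next
    }
    if (any(ij %in% usedIdx)) {
      harmonics <- c(harmonics, list(ij))
    } else {
      dep <- FALSE
      for (c0 in usedIdx) {
        for (v0 in ij) {
          if (polyDep(V[, c0], V[, v0]) >= depMax) { dep <- TRUE; break }
        }
        if (dep) break
      }
      if (dep) {
        rejected <- c(rejected, list(ij))
      } else {
        cms <- c(cms, list(ij))
        usedIdx <- c(usedIdx, ij)
      }
    }
  }
  if (!length(cms))
    message("no subspace reached R^2 >= ", r2Min,
            ": embedding appears globular (no usable geometric structure)")
  new("CMCatalog", cms = cms, harmonics = harmonics, rejected = rejected,
      fits = fits, nFound = length(cms), r2Min = r2Min)
}

#' Essential rotation planes for realigning a CM catalog
#'
#' With n CMs found there are choose(n, 2) essential operators, one per CM
#' pair. Mode "lower" returns the plane pairing the two CMs' leading
#' eigenvector indices; mode "cross" returns all four index pairings per CM
#' pair (useful because the mixed pair is not always the leading one).
#' A single CM needs (and permits) no realignment: the result is empty.
#'
#' @param catalog a [CMCatalog-class].
#' @param d embedding dimensionality (bounds check only).
#' @param mode "lower" or "cross".
#' @return list of integer(2) planes (i < j).
#' @export
essentialOperators <- function(catalog, d, mode = c("lower", "cross")) {
  mode <- match.arg(mode)
  cms <- cmSubspaces(catalog)
  n <- length(cms)
  if (n < 2) return(list())
  planes <- list()
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (mode == "lower") {
      pl <- sort(c(cms[[a]][1], cms[[b]][1]))
      planes <- c(planes, list(as.integer(pl)))
    } else {
      for (u in cms[[a]]) for (v in cms[[b]])
        planes <- c(planes, list(as.integer(sort(c(u, v)))))
    }
  }
  stopifnot(all(vapply(planes, max, 0) <= d))
  planes
}

## rotate eigenvector columns (i, j) by theta degrees:
## vi' = cos(t) vi - sin(t) vj ; vj' = sin(t) vi + cos(t) vj
## (the counter-rotation of the canonical eigenbasis mixing convention)
.rotateColumns <- function(V, i, j, thetaDeg) {
  t <- thetaDeg * pi / 180
  vi <- V[, i]; vj <- V[, j]
  V[, i] <- cos(t) * vi - sin(t) * vj
  V[, j] <- sin(t) * vi + cos(t) * vj
  V
}

#' Histogram-based search for the counter-rotation angle of one plane
#'
#' For each candidate angle the plane's two eigenvector columns are
#' rotated, every affected CM subspace is binned into a 2D histogram whose
#' bounding box is frozen at theta = 0 (so counts are comparable across
#' angles), and the nonzero bins are counted and summed over subspaces.
#' The angle minimizing the count concentrates the point clouds onto their
#' one-dimensional parabolic loci and is returned as the counter-rotation;
#' ties break toward the smallest magnitude. A flat count profile (spread
#' below one bin) means no realignment is needed: 0 is returned with
#' attribute `noRealignment`.
#'
#' @param emb an [Embedding-class].
#' @param plane integer(2) eigenvector index pair (i < j).
#' @param thetaGrid candidate angles in degrees (default -90..89 step 1).
#' @param bins histogram bins per axis (>= 20).
#' @param subspaces list of CM subspaces to score (default: the plane
#'   itself); subspaces not touching the plane are ignored.
#' @return optimal angle theta* in degrees.
#' @export
histogramAngleSearch <- function(emb, plane, thetaGrid = seq(-90, 89, by = 1),
                                 bins = 40L, subspaces = NULL) {
  stopifnot(length(plane) == 2, plane[1] < plane[2], bins >= 20)
  if (max(abs(diff(thetaGrid))) > 1 + 1e-9)
    stop("thetaGrid must cover [-90, 90) at step <= 1 degree")
  V <- eigVectors(emb)
  if (is.null(subspaces)) subspaces <- list(as.integer(plane))
  touched <- Filter(function(s) any(s %in% plane), subspaces)
  if (!length(touched)) touched <- list(as.integer(plane))
  pad <- function(v) {
    r <- range(v); m <- diff(r) * 0.5 + 1e-12
    c(r[1] - m, r[2] + m)  # generous box: rotated clouds must stay inside
  }
  boxes <- lapply(touched, function(s)
    list(xlim = pad(V[, s[1]]), ylim = pad(V[, s[2]])))
  counts <- vapply(thetaGrid, function(th) {
    Vr <- .rotateColumns(V, plane[1], plane[2], th)
    sum(vapply(seq_along(touched), function(q) {
      s <- touched[[q]]
      nonzeroBins2D(cbind(Vr[, s[1]], Vr[, s[2]]), boxes[[q]], bins)
    }, numeric(1)))
  }, numeric(1))
  if (diff(range(counts)) < 1) {
    out <- 0
    attr(out, "noRealignment") <- TRUE
    return(out)
  }
  best <- which(counts == min(counts))
  best <- best[order(abs(thetaGrid[best]), thetaGrid[best])][1]
  thetaGrid[best]
}

#' Apply an ordered plan of planar rotations to an embedding
#'
#' Operators are applied left to right; only the named columns change and
#' column norms are preserved (each step is orthogonal).
#'
#' @param emb an [Embedding-class].
#' @param plan a [RotationPlan-class].
#' @return rotated [Embedding-class].
#' @export
applyRotationPlan <- function(emb, plan) {
  V <- eigVectors(emb)
  ops <- plan@ops
  for (r in seq_len(nrow(ops)))
    V <- .rotateColumns(V, ops$i[r], ops$j[r], ops$theta[r])
  initialize(emb, eigvecs = V)
}

#' Invert a rotation plan
#'
#' Reverses the operator order and negates each angle, so applying a plan
#' followed by its inverse is the identity.
#'
#' @param plan a [RotationPlan-class].
#' @export
invertPlan <- function(plan) {
  ops <- plan@ops[rev(seq_len(nrow(plan@ops))), , drop = FALSE]
  ops$theta <- -ops$theta
  ops$theta[ops$theta == 90] <- -90   # keep within [-90, 90)
  rownames(ops) <- NULL
  new("RotationPlan", ops = ops, d = plan@d)
}

#' Realign misaligned eigenfunctions by composed planar rotations
#'
#' For every essential operator plane (all four cross pairings of each pair
#' of CM subspaces by default), runs [histogramAngleSearch] and applies the
#' counter-rotation, then refits all CM subspaces. An operator whose
#' application decreases any CM subspace fit by more than `tol` is reverted
#' with a warning, so the post-rotation R^2 of every CM subspace is at
#' least its pre-rotation value minus `tol`.
#'
#' @param emb an [Embedding-class].
#' @param catalog a non-empty [CMCatalog-class].
#' @param mode operator enumeration mode (see [essentialOperators]).
#' @param bins,thetaGrid passed to [histogramAngleSearch].
#' @param constraint conic mode for refits.
#' @param tol permitted per-operator R^2 decrease before reverting.
#' @return list with elements `embedding` (rotated), `plan`
#'   (a [RotationPlan-class] of applied operators) and `fits` (refreshed
#'   [ConicFit-class] per CM).
#' @export
realignEigenbasis <- function(emb, catalog, mode = "cross", bins = 40L,
                              thetaGrid = seq(-90, 89, by = 1),
                              constraint = "parabola", tol = 0.01) {
  if (catalog@nFound < 1) stop("catalog is empty: nothing to realign")
  cms <- cmSubspaces(catalog)
  d <- ncol(eigVectors(emb))
  planes <- essentialOperators(catalog, d, mode)
  refit <- function(e) vapply(cms, function(s)
    fitConic(eigVectors(e)[, s, drop = FALSE], constraint)@r2, numeric(1))
  ops <- data.frame(i = integer(), j = integer(), theta = numeric())
  cur <- emb
  curR2 <- refit(cur)
  for (pl in planes) {
    th <- histogramAngleSearch(cur, pl, thetaGrid, bins, subspaces = cms)
    if (isTRUE(attr(th, "noRealignment")) || th == 0) next
    cand <- applyRotationPlan(cur, new("RotationPlan",
      ops = data.frame(i = pl[1], j = pl[2], theta = as.numeric(th)),
      d = as.integer(d)))
    candR2 <- refit(cand)
    if (min(candR2 - curR2) < -tol) {
      warning(sprintf(
        "reverting R_{%d,%d}(%g): CM fit would drop by %.3f",
        pl[1], pl[2], th, -min(candR2 - curR2)))
      next
    }
    cur <- cand
    curR2 <- candR2
    ops <- rbind(ops, data.frame(i = pl[1], j = pl[2],
                                 theta = as.numeric(th)))
  }
  fits <- lapply(seq_along(cms), function(k) {
    f <- fitConic(eigVectors(cur)[, cms[[k]], drop = FALSE], constraint)
    f@subspace <- as.integer(cms[[k]])
    f
  })
  list(embedding = cur,
       plan = new("RotationPlan", ops = ops, d = as.integer(d)),
       fits = fits)
}
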