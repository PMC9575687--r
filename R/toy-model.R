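#' @include AllClasses.R geometry-utils.R
NULL

## Deterministic small off-axis jitter so domains are not exactly collinear;
## purely a function of the atom index.
.chainJitter <- function(k, scale = 0.6) {
  cbind(scale * sin(1.7 * k), scale * cos(2.3 * k), scale * sin(0.9 * k + 1))
}

#' Build a pseudo-atomic toy model
#'
#' Two presets are available. `two_arm_v` is a V-shaped machine: a static
#' core at the base plus two arm-like domains, each rotating rigidly about
#' its own hinge axis (arm 1 in the projection plane of the default view,
#' arm 2 out of plane, so the two motions foreshorten differently across
#' projection directions). `mouth_wings` exercises concerted per-atom
#' translations instead of rigid rotations: a "mouth" whose upper and lower
#' halves translate apart, and "wings" whose left and right clusters
#' translate along different directions; inter-atom distances within each
#' group change under motion.
#'
#' Default hinge ranges are 0 to 40 degrees per conformational motion;
#' translation ranges are the motion coordinate 0 to 1. Coordinates are in
#' pixel units with the model centered so that all states stay inside a
#' 64-pixel box under arbitrary viewing rotations.
#'
#' @param preset "two_arm_v" or "mouth_wings".
#' @param atomsPerDomain integer >= 3, pseudo-atoms per domain.
#' @return a [ToyModel-class].
#' @examples
#' m <- buildToyModel("two_arm_v", atomsPerDomain = 12)
#' @export
buildToyModel <- function(preset = c("two_arm_v", "mouth_wings"),
                          atomsPerDomain = 12L) {
  preset <- tryCatch(match.arg(preset),
                     error = function(e) stop("unknown preset: ",
                                              preset[1], call. = FALSE))
  if (atomsPerDomain < 3) stop("atomsPerDomain must be >= 3")
  k <- seq_len(atomsPerDomain)
  if (preset == "two_arm_v") {
    ## static core: compact cluster at the base of the V; deliberately
    ## lighter than the arms so the conformational signal dominates the
    ## image power (as for a machine whose moving domains are large)
    nc <- 4L
    kc <- seq_len(nc)
    core <- cbind(2 * sin(2.1 * kc), -9 + 4 * (kc - 1) / nc,
                  2 * cos(1.3 * kc))
    ## arms: three-strand chains (thick, heavy domains)
    strand <- function(anchor, dir, jitterOff) {
      t1 <- 2 + 22 * (k - 1) / (atomsPerDomain - 1)
      perp <- c(-dir[2], dir[1], 0)
      base <- sweep(outer(t1, dir), 2, anchor, "+")
      rbind(base + matrix(1.6 * perp, atomsPerDomain, 3,
                          byrow = TRUE) + .chainJitter(k + jitterOff),
            base + .chainJitter(k + jitterOff + 23),
            base - matrix(1.6 * perp, atomsPerDomain, 3,
                          byrow = TRUE) + .chainJitter(k + jitterOff + 11))
    }
    ## arm 1: up-left in the xy-plane; hinge about +z at its anchor
    a1 <- c(-1.5, -3, 0)
    d1 <- c(-1, 1, 0) / sqrt(2)
    arm1 <- strand(a1, d1, 0)
    ## arm 2: up-right; hinge axis tilted out of the viewing plane so the
    ## motion sweeps a different plane than arm 1 yet stays first-order
    ## visible from generic viewing directions
    a2 <- c(1.5, -3, 0)
    d2 <- c(1, 1, 0) / sqrt(2)
    arm2 <- strand(a2, d2, 37)
    atoms <- rbind(core, arm1, arm2)
    domain <- c(rep(0L, nc), rep(1L, 3 * atomsPerDomain),
                rep(2L, 3 * atomsPerDomain))
    hinges <- list(
      list(mode = "hinge", anchor = a1, axis = c(0, 0, 1),
           range = c(0, 40)),
      list(mode = "hinge", anchor = a2, axis = c(1, 0, 1) / sqrt(2),
           range = c(0, 40)))
  } else {
    ## mouth-wings: motions are displacement fields, not rigid rotations
    core <- cbind(3 * sin(1.9 * k), 3 * cos(1.1 * k), 2 * sin(2.7 * k))
    half <- ceiling(atomsPerDomain / 2)
    upper <- k <= half
    ## mouth: a ring of atoms; upper half translates up+out, lower half down
    ang <- 2 * pi * (k - 1) / atomsPerDomain
    mouth <- cbind(6 * cos(ang), -8 + 2 * sin(ang), 2 * sin(2 * ang))
    dispM <- cbind(rep(0, atomsPerDomain),
                   ifelse(upper, 6, -6),
                   ifelse(upper, 2, -2))
    ## wings: two lateral clusters translating along different directions
    lw <- k <= half
    wings <- cbind(ifelse(lw, -12, 12) + 2 * sin(3 * k),
                   6 + 3 * cos(1.7 * k), 2 * cos(2.2 * k))
    dispW <- cbind(ifelse(lw, -5, 5), rep(4, atomsPerDomain),
                   ifelse(lw, 3, -3))
    atoms <- rbind(core, mouth, wings)
    domain <- rep(0:2, each = atomsPerDomain)
    hinges <- list(
      list(mode = "translation", anchor = c(0, 0, 0), axis = c(0, 1, 0),
           range = c(0, 1), disp = dispM),
      list(mode = "translation", anchor = c(0, 0, 0), axis = c(0, 1, 0),
           range = c(0, 1), disp = dispW))
  }
  new("ToyModel", atoms = atoms, domain = as.integer(domain),
      hinges = hinges, preset = preset)
}

#' Enumerate the discretized state space of a toy model
#'
#' State s along CM gamma (s in 0..M-1) exercises motion value
#' `min + s * (max - min) / (M - 1)` of that domain's range, so the M
#' values are equispaced and include both endpoints. States are enumerated
#' in row-major order over the multi-index (s1, ..., sn) (last index
#' fastest).
#'
#' @param model a [ToyModel-class].
#' @param n number of conformational motions to exercise (<= mobile domains).
#' @param M states per CM (>= 2).
#' @return a [StateSpace-class].
#' @examples
#' ss <- generateStateSpace(buildToyModel("two_arm_v"), n = 2, M = 20)
#' @export
generateStateSpace <- function(model, n, M = 20L) {
  n <- as.integer(n); M <- as.integer(M)
  if (n > length(model@hinges))
    stop("n exceeds the number of mobile domains (",
         length(model@hinges), ")")
  if (M < 2) stop("M must be >= 2")
  grids <- lapply(seq_len(n), function(g) {
    r <- model@hinges[[g]]$range
    seq(r[1], r[2], length.out = M)
  })
  ## row-major: last CM index varies fastest
  idx <- as.matrix(rev(expand.grid(rev(lapply(seq_len(n),
                                              function(i) 0:(M - 1L))))))
  colnames(idx) <- paste0("state", seq_len(n))
  ang <- vapply(seq_len(n), function(g) grids[[g]][idx[, g] + 1L],
                numeric(nrow(idx)))
  ang <- matrix(ang, ncol = n)
  colnames(ang) <- paste0("angle", seq_len(n))
  new("StateSpace", n = n, M = M, states = idx, angles = ang)
}

#' Atom coordinates of a model in a given state
#'
#' @param model a [ToyModel-class].
#' @param angles numeric vector of motion values, one per exercised CM
#'   (trailing mobile domains stay at their range minimum).
#' @return nAtoms x 3 coordinate matrix.
#' @export
stateCoordinates <- function(model, angles) {
  coords <- model@atoms
  for (g in seq_along(model@hinges)) {
    h <- model@hinges[[g]]
    val <- if (g <= length(angles)) angles[g] else h$range[1]
    sel <- model@domain == g
    if (h$mode == "hinge") {
      R <- axisAngleMatrix(h$axis, val)
      coords[sel, ] <- sweep(sweep(coords[sel, , drop = FALSE], 2, h$anchor) %*%
                               t(R), 2, h$anchor, "+")
    } else {
      coords[sel, ] <- coords[sel, , drop = FALSE] + val * h$disp
    }
  }
  coords
}

#' Render the 3D density of one conformational state
#'
#' Each pseudo-atom becomes an isotropic unit-integral Gaussian blob. The
#' grid origin is at the geometric center of the `gridSize`^3 voxel cube.
#'
#' @param model a [ToyModel-class].
#' @param angles motion values per CM (see [stateCoordinates]).
#' @param gridSize cubic grid side in voxels.
#' @param blobSigma Gaussian blob sigma in voxels.
#' @return gridSize^3 numeric array, nonnegative.
#' @export
renderDensity <- function(model, angles, gridSize = 64L, blobSigma = 1.5) {
  coords <- stateCoordinates(model, angles)
  ctr <- (gridSize - 1) / 2
  pos <- coords + ctr
  bad <- which(pos < 0 | pos > gridSize - 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "atom %d falls outside the %d^3 grid in state (%s)",
      bad[1, 1], gridSize, paste(signif(angles, 4), collapse = ", ")))
  }
  ax <- seq_len(gridSize) - 1
  vol <- array(0, rep(gridSize, 3))
  nrm <- (2 * pi * blobSigma^2)^(-3 / 2)
  for (a in seq_len(nrow(pos))) {
    gx <- exp(-(ax - pos[a, 1])^2 / (2 * blobSigma^2))
    gy <- exp(-(ax - pos[a, 2])^2 / (2 * blobSigma^2))
    gz <- exp(-(ax - pos[a, 3])^2 / (2 * blobSigma^2))
    vol <- vol + nrm * (gx %o% gy %o% gz)
  }
  vol
}

#' Project a cubic volume along +z after rotating it
#'
#' The volume is resampled under the rotation given by the projection
#' direction's quaternion (trilinear interpolation about the grid center)
#' and then summed along the third axis, i.e. a line integral along +z.
#'
#' @param volume cubic numeric array.
#' @param quaternion numeric(4) unit quaternion (w, x, y, z) rotating the
#'   object frame into the viewing frame, or a
#'   [ProjectionDirections-class] plus `which` selecting one PD.
#' @param which PD index when `quaternion` is a ProjectionDirections set.
#' @return P x P projection image (dim 1 = x, dim 2 = y).
#' @export
projectVolume <- function(volume, quaternion = c(1, 0, 0, 0), which = 1L) {
  d <- dim(volume)
  if (length(d) != 3 || length(unique(d)) != 1) stop("volume must be cubic")
  if (is(quaternion, "ProjectionDirections"))
    quaternion <- quaternion@quaternion[which, ]
  G <- d[1]
  R <- quatToMatrix(quaternion)
  if (max(abs(R - diag(3))) < 1e-12) return(rowSums(volume, dims = 2))
  ctr <- (G - 1) / 2
  ax <- (seq_len(G) - 1) - ctr
  grid <- cbind(rep(ax, times = G * G),
                rep(rep(ax, each = G), times = G),
                rep(ax, each = G * G))
  ## rotated volume V'(p) = V(R^T p): sample source at R^T p
  src <- grid %*% R + ctr
  x <- src[, 1]; y <- src[, 2]; z <- src[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  val <- numeric(length(x))
  inb <- function(i) pmin(pmax(i, 0), G - 1)
  at <- function(i, j, k) {
    ok <- i >= 0 & i <= G - 1 & j >= 0 & j <= G - 1 & k >= 0 & k <= G - 1
    out <- numeric(length(i))
    idx <- 1 + inb(i) + G * inb(j) + G * G * inb(k)
    out[ok] <- volume[idx[ok]]
    out
  }
  val <- at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    at(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    at(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    at(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    at(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    at(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    at(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  rot <- array(val, dim = d)
  rowSums(rot, dims = 2)
}

#' Analytic projection image of a model state
#'
#' Equivalent to rendering the 3D density and projecting, but exact: the
#' line integral of a unit-integral 3D Gaussian is a unit-integral 2D
#' Gaussian, so atoms are rotated and rendered directly in 2D.
#'
#' @inheritParams renderDensity
#' @param quaternion unit quaternion of the viewing rotation.
#' @param P image side in pixels.
#' @return P x P image.
#' @export
renderProjection <- function(model, angles, quaternion = c(1, 0, 0, 0),
                             P = 64L, blobSigma = 1.5) {
  coords <- stateCoordinates(model, angles) %*% t(quatToMatrix(quaternion))
  ctr <- (P - 1) / 2
  pos <- coords[, 1:2, drop = FALSE] + ctr
  ax <- seq_len(P) - 1
  img <- matrix(0, P, P)
  nrm <- 1 / (2 * pi * blobSigma^2)
  for (a in seq_len(nrow(pos))) {
    gx <- exp(-(ax - pos[a, 1])^2 / (2 * blobSigma^2))
    gy <- exp(-(ax - pos[a, 2])^2 / (2 * blobSigma^2))
    img <- img + nrm * (gx %o% gy)
  }
  img
}
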