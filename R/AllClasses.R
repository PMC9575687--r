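#' @import methods
NULL

#' Pseudo-atomic toy model of a molecular machine
#'
#' A `ToyModel` holds a small set of pseudo-atoms grouped into rigid bodies:
#' a static core (domain 0) plus one or more mobile domains. Each mobile
#' domain carries one motion descriptor: either a hinge (anchor point, unit
#' axis and an angular range in degrees about which the whole domain rotates
#' rigidly) or a per-atom displacement field exercised over a scalar range
#' (used by the `mouth_wings` preset, whose motions are concerted
#' translations rather than rigid rotations).
#'
#' @slot atoms numeric matrix (nAtoms x 3) of pseudo-atom coordinates in the
#'   reference (zero-angle) state, in arbitrary length units (treated as
#'   voxel/pixel units at render time).
#' @slot domain integer vector, one label per atom; 0 is the static core,
#'   labels >= 1 are mobile domains.
#' @slot hinges list, one element per mobile domain, each a list with fields
#'   `mode` ("hinge" or "translation"), `anchor`, `axis` (unit vector),
#'   `range` (c(min, max), degrees for hinges, dimensionless motion
#'   coordinate for translations) and, for translations, `disp` (nAtoms x 3
#'   displacement applied at unit motion coordinate).
#' @slot preset character, name of the construction preset.
#' @export
setClass("ToyModel",
  representation(atoms = "matrix", domain = "integer", hinges = "list",
                 preset = "character"))

setValidity("ToyModel", function(object) {
  msg <- character()
  if (ncol(object@atoms) != 3L) msg <- c(msg, "atoms must be an n x 3 matrix")
  if (length(object@domain) != nrow(object@atoms))
    msg <- c(msg, "one domain label per atom required")
  nmob <- length(object@hinges)
  if (nmob > 0 && !setequal(seq_len(nmob), unique(object@domain[object@domain > 0])))
    msg <- c(msg, "mobile domain labels must be 1..length(hinges)")
  for (h in object@hinges) {
    if (h$mode == "hinge" && abs(sqrt(sum(h$axis^2)) - 1) > 1e-8)
      msg <- c(msg, "hinge axis must have unit norm")
    if (diff(h$range) < 0) msg <- c(msg, "motion range must be nondecreasing")
  }
  tab <- table(object@domain)
  if (any(tab < 3)) msg <- c(msg, "every domain needs at least 3 atoms")
  if (length(msg)) msg else TRUE
})

#' Discretized conformational state space
#'
#' Enumerates the M^n states of a machine exercising n independent
#' conformational motions (CMs), each discretized into M equispaced motion
#' values across its range. States are stored in row-major order over the
#' multi-index (s1, ..., sn), each s in 0..M-1.
#'
#' @slot n integer, intrinsic dimensionality (number of CMs).
#' @slot M integer, states per CM.
#' @slot states integer matrix (M^n x n) of 0-based state indices.
#' @slot angles numeric matrix (M^n x n): the motion value (hinge angle in
#'   degrees, or translation coordinate) of each CM in each state.
#' @export
setClass("StateSpace",
  representation(n = "integer", M = "integer", states = "matrix",
                 angles = "matrix"))

setValidity("StateSpace", function(object) {
  if (nrow(object@states) != object@M^object@n)
    return("state count must equal M^n")
  TRUE
})

#' Set of projection directions on the sphere
#'
#' @slot id integer vector of PD identifiers.
#' @slot quaternion numeric matrix (nPD x 4), unit quaternions (w, x, y, z);
#'   the rotation applied to the model before projecting along +z.
#' @slot apertureDeg numeric, angular aperture width on the sphere.
#' @export
setClass("ProjectionDirections",
  representation(id = "integer", quaternion = "matrix", apertureDeg = "numeric"))

setValidity("ProjectionDirections", function(object) {
  if (ncol(object@quaternion) != 4L) return("quaternions must be nPD x 4")
  nrm <- sqrt(rowSums(object@quaternion^2))
  if (any(abs(nrm - 1) > 1e-8)) return("quaternions must be unit-norm")
  if (object@apertureDeg <= 0) return("apertureDeg must be positive")
  TRUE
})

#' Microscope / imaging parameters for CTF simulation
#'
#' @slot voltageKV numeric, acceleration voltage in kV.
#' @slot csMM numeric, spherical aberration in mm.
#' @slot amplitudeContrast numeric fraction in [0, 1).
#' @slot pixelSizeA numeric, pixel size in Angstrom.
#' @slot defocusRangeUM numeric length-2, defocus range in micrometer
#'   (positive = underfocus).
#' @export
setClass("MicroscopeParams",
  representation(voltageKV = "numeric", csMM = "numeric",
                 amplitudeContrast = "numeric", pixelSizeA = "numeric",
                 defocusRangeUM = "numeric"))

setValidity("MicroscopeParams", function(object) {
  if (object@voltageKV <= 0 || object@csMM <= 0 || object@pixelSizeA <= 0)
    return("voltage, Cs and pixel size must be positive")
  if (object@amplitudeContrast < 0 || object@amplitudeContrast >= 1)
    return("amplitude contrast must be a fraction in [0, 1)")
  if (length(object@defocusRangeUM) != 2L ||
      diff(object@defocusRangeUM) < 0)
    return("defocusRangeUM must be c(min, max) with min <= max")
  TRUE
})

#' Per-state image abundance specification
#'
#' Uniform mode repeats every state tau times; weighted mode draws image
#' counts from nonnegative per-state weights (nonuniform occupancy).
#'
#' @slot mode character, "uniform" or "weighted".
#' @slot tau integer, copies per state (uniform mode).
#' @slot weights numeric vector, one nonnegative weight per state (weighted
#'   mode); empty in uniform mode.
#' @export
setClass("OccupancySpec",
  representation(mode = "character", tau = "integer", weights = "numeric"))

setValidity("OccupancySpec", function(object) {
  if (!object@mode %in% c("uniform", "weighted"))
    return("mode must be 'uniform' or 'weighted'")
  if (object@mode == "uniform" && object@tau < 1L)
    return("tau must be an integer >= 1")
  if (object@mode == "weighted" &&
      (any(object@weights < 0) || sum(object@weights) <= 0))
    return("weights must be nonnegative with positive sum")
  TRUE
})

#' Stack of projection images with ground-truth metadata
#'
#' @slot images numeric array (P x P x N).
#' @slot pixelSizeA numeric pixel size in Angstrom.
#' @slot meta data.frame with one row per image; columns include imageId,
#'   pdId, state indices (state1, ...), defocusUM, snr, noiseSeed.
#' @export
setClass("ImageStack",
  representation(images = "array", pixelSizeA = "numeric", meta = "data.frame"))

setValidity("ImageStack", function(object) {
  d <- dim(object@images)
  if (length(d) != 3L) return("images must be a P x P x N array")
  if (d[1] != d[2]) return("images must be square")
  if (d[1] %% 2L != 0L) return("image side P must be even")
  if (nrow(object@meta) != d[3]) return("meta must have one row per image")
  if (anyNA(object@images) || any(!is.finite(object@images)))
    return("images must be finite")
  if (anyDuplicated(object@meta$imageId)) return("imageId must be unique")
  TRUE
})

#' Pairwise image distance matrix
#'
#' @slot D numeric N x N symmetric nonnegative matrix with zero diagonal.
#' @slot method character, "plain" or "double_filter".
#' @export
setClass("DistanceMatrix",
  representation(D = "matrix", method = "character"))

setValidity("DistanceMatrix", function(object) {
  if (max(abs(object@D - t(object@D))) > 1e-10) return("D must be symmetric")
  if (any(abs(diag(object@D)) > 1e-12)) return("diagonal of D must be zero")
  if (any(object@D < -1e-12)) return("D must be nonnegative")
  TRUE
})

#' Low-dimensional spectral embedding of one PD manifold
#'
#' Columns of `eigvecs` are the nontrivial leading eigenvectors (the
#' constant mode of the diffusion operator is removed), unit-normalized,
#' sign-fixed so each column's third moment is nonnegative.
#'
#' @slot eigvals numeric, descending.
#' @slot eigvecs numeric matrix N x d.
#' @slot epsilon numeric Gaussian kernel bandwidth (NA for PCA).
#' @slot method character, "DM" or "PCA".
#' @slot pdId integer PD identifier.
#' @export
setClass("Embedding",
  representation(eigvals = "numeric", eigvecs = "matrix", epsilon = "numeric",
                 method = "character", pdId = "integer"))

setValidity("Embedding", function(object) {
  if (length(object@eigvals) != ncol(object@eigvecs))
    return("one eigenvalue per eigenvector column required")
  if (is.unsorted(rev(object@eigvals), strictly = FALSE))
    return("eigenvalues must be sorted descending")
  TRUE
})

#' Conic-section fit of a 2D subspace point cloud
#'
#' Coefficients (a, b, c, d, e, f) of ax^2 + bxy + cy^2 + dx + ey + f = 0,
#' normalized to unit norm in general mode. In parabola mode the fit is the
#' functional form y = a x^2 + b x + c (d = -b, e = -1, f = -c stored in the
#' implicit coefficients with unit normalization).
#'
#' @slot coefficients named numeric(6).
#' @slot r2 numeric goodness of fit (1 is perfect; can be negative).
#' @slot subspace integer(2), eigenvector indices (i, j), i < j.
#' @slot mode character, "parabola" or "general".
#' @slot degenerate logical, TRUE when the input was (near) collinear.
#' @export
setClass("ConicFit",
  representation(coefficients = "numeric", r2 = "numeric",
                 subspace = "integer", mode = "character",
                 degenerate = "logical"))

#' Catalog of conformational-motion subspaces found in an embedding
#'
#' @slot cms list of integer(2) subspaces, one per CM found, in acceptance
#'   order (CM_1 first); pairwise index-disjoint.
#' @slot harmonics list of integer(2) subspaces excluded because they share
#'   an eigenvector index with an accepted CM (parabolic harmonics).
#' @slot rejected list of integer(2) index-disjoint parabolic subspaces
#'   rejected because one of their eigenvectors is functionally dependent
#'   on an accepted CM's eigenvector (higher-order parabolas repeating an
#'   already-found motion).
#' @slot fits list of ConicFit for all scanned subspaces.
#' @slot nFound integer, number of CMs found.
#' @slot r2Min numeric gate used.
#' @export
setClass("CMCatalog",
  representation(cms = "list", harmonics = "list", rejected = "list",
                 fits = "list", nFound = "integer", r2Min = "numeric"))

setValidity("CMCatalog", function(object) {
  idx <- unlist(object@cms)
  if (anyDuplicated(idx)) return("CM subspaces must be pairwise index-disjoint")
  for (h in object@harmonics)
    if (!any(h %in% idx))
      return("every harmonic must share an index with some CM subspace")
  TRUE
})

#' Ordered plan of planar (Givens-type) eigenbasis rotations
#'
#' @slot ops data.frame with columns i, j (plane, i < j) and theta
#'   (degrees in [-90, 90)), applied in row order.
#' @slot d integer, embedding dimensionality the plan acts on.
#' @export
setClass("RotationPlan",
  representation(ops = "data.frame", d = "integer"))

setValidity("RotationPlan", function(object) {
  if (nrow(object@ops) == 0) return(TRUE)
  if (any(object@ops$i >= object@ops$j)) return("plane indices must satisfy i < j")
  if (any(object@ops$j > object@d)) return("plane indices must be <= d")
  if (any(object@ops$theta < -90 | object@ops$theta >= 90))
    return("theta must lie in [-90, 90)")
  TRUE
})

#' Equal-area partition of a CM subspace
#'
#' @slot B integer number of bins.
#' @slot subPolygons list of B polygon matrices (two columns, closed
#'   implicitly), contiguous and equal-area, ordered along the ray sweep.
#' @slot binOfImage integer vector in 1..B (lower-index bin on boundaries).
#' @slot occupancy numeric vector of per-bin point counts.
#' @slot alphaPolygon numeric matrix, enclosing alpha-shape polygon.
#' @slot anchor numeric(2) ray-sweep anchor point.
#' @slot outside logical vector flagging points outside the alpha polygon
#'   (assigned to the nearest bin).
#' @slot cutAngles numeric, the B-1 interior cut-ray angles (radians).
#' @export
setClass("BinSet",
  representation(B = "integer", subPolygons = "list", binOfImage = "integer",
                 occupancy = "numeric", alphaPolygon = "matrix",
                 anchor = "numeric", outside = "logical",
                 cutAngles = "numeric"))

setValidity("BinSet", function(object) {
  if (length(object@subPolygons) != object@B)
    return("need exactly B sub-polygons")
  if (sum(object@occupancy) != sum(!is.na(object@binOfImage)))
    return("occupancy must sum to the number of assigned images")
  TRUE
})

#' Per-bin averaged-image 2D movie of one conformational motion
#'
#' @slot frames numeric array (P x P x B); frame b is the pixel mean of the
#'   raw images assigned to bin b.
#' @slot cmId integer CM label.
#' @slot pdId integer PD label.
#' @slot sense integer +1/-1 playback direction.
#' @slot empty logical vector flagging empty bins (zero frames).
#' @export
setClass("Movie2D",
  representation(frames = "array", cmId = "integer", pdId = "integer",
                 sense = "integer", empty = "logical"))

#' Global CM-label and sense assignment across PDs
#'
#' @slot assignments data.frame with columns pdId, cmLocal, cmGlobal,
#'   sense (+1/-1), confidence, ambiguous (logical).
#' @export
setClass("SenseMap", representation(assignments = "data.frame"))

#' n-dimensional per-state occupancy map
#'
#' @slot counts integer/numeric n-dimensional array (B cells per axis).
#' @slot contributingPDs integer vector of PDs passing the R^2 gate.
#' @slot gate numeric R^2 threshold used.
#' @export
setClass("OccupancyMapND",
  representation(counts = "array", contributingPDs = "integer",
                 gate = "numeric"))

#' Free-energy landscape in units of kT
#'
#' @slot deltaG numeric n-dimensional array; NA where counts were zero.
#' @slot mask logical array, TRUE where the landscape is defined.
#' @slot referenceBin integer vector, multi-index of the max-occupancy cell.
#' @slot kT numeric thermal energy unit.
#' @export
setClass("EnergyLandscape",
  representation(deltaG = "array", mask = "array", referenceBin = "integer",
                 kT = "numeric"))

setValidity("EnergyLandscape", function(object) {
  v <- object@deltaG[object@mask]
  if (length(v) && abs(min(v)) > 1e-9)
    return("minimum over unmasked bins must be zero")
  TRUE
})

#' Manifest of exported per-state image stacks
#'
#' @slot entries data.frame with columns state (label), stackPath,
#'   alignmentPath, nImages.
#' @slot imageIds list of integer image-id vectors, one per state.
#' @export
setClass("StateStackManifest",
  representation(entries = "data.frame", imageIds = "list"))

#' Flat run configuration with provenance stamp
#'
#' Round-trips losslessly through a flat key=value text file; unknown keys
#' are rejected on read.
#'
#' @slot values named list of parameters.
#' @slot hash character provenance hash of the canonical text form.
#' @export
setClass("RunConfig", representation(values = "list", hash = "character"))
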