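#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the package's S4 containers. Slot access via
#' `@` is considered internal.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("images", function(x) standardGeneric("images"))
#' @rdname accessors
#' @export
setGeneric("imageMeta", function(x) standardGeneric("imageMeta"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))
#' @rdname accessors
#' @export
setGeneric("eigVectors", function(x) standardGeneric("eigVectors"))
#' @rdname accessors
#' @export
setGeneric("eigValues", function(x) standardGeneric("eigValues"))
#' @rdname accessors
#' @export
setGeneric("cmSubspaces", function(x) standardGeneric("cmSubspaces"))
#' @rdname accessors
#' @export
setGeneric("occupancyCounts", function(x) standardGeneric("occupancyCounts"))
#' @rdname accessors
#' @export
setGeneric("energies", function(x) standardGeneric("energies"))
#' @rdname accessors
#' @export
setGeneric("binOccupancy", function(x) standardGeneric("binOccupancy"))
#' @rdname accessors
#' @export
setGeneric("movieFrames", function(x) standardGeneric("movieFrames"))

#' @rdname accessors
#' @export
setMethod("images", "ImageStack", function(x) x@images)
#' @rdname accessors
#' @export
setMethod("imageMeta", "ImageStack", function(x) x@meta)
#' @rdname accessors
#' @export
setMethod("pixelSize", "ImageStack", function(x) x@pixelSizeA)
#' @rdname accessors
#' @export
setMethod("nImages", "ImageStack", function(x) dim(x@images)[3])
#' @rdname accessors
#' @export
setMethod("eigVectors", "Embedding", function(x) x@eigvecs)
#' @rdname accessors
#' @export
setMethod("eigValues", "Embedding", function(x) x@eigvals)
#' @rdname accessors
#' @export
setMethod("cmSubspaces", "CMCatalog", function(x) x@cms)
#' @rdname accessors
#' @export
setMethod("occupancyCounts", "OccupancyMapND", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("energies", "EnergyLandscape", function(x) x@deltaG)
#' @rdname accessors
#' @export
setMethod("binOccupancy", "BinSet", function(x) x@occupancy)
#' @rdname accessors
#' @export
setMethod("movieFrames", "Movie2D", function(x) x@frames)

setMethod("show", "ToyModel", function(object) {
  cat("ToyModel '", object@preset, "': ", nrow(object@atoms), " pseudo-atoms, ",
      length(object@hinges), " mobile domain(s) + core\n", sep = "")
})

setMethod("show", "StateSpace", function(object) {
  cat("StateSpace: n =", object@n, "CMs x M =", object@M,
      "states =", nrow(object@states), "states total\n")
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@images)
  cat("ImageStack: ", d[3], " images of ", d[1], " x ", d[2], " px (",
      object@pixelSizeA, " A/px)\n", sep = "")
})

setMethod("show", "Embedding", function(object) {
  cat(object@method, " embedding of PD ", object@pdId, ": ",
      nrow(object@eigvecs), " points x ", ncol(object@eigvecs),
      " eigenvectors\n", sep = "")
})

setMethod("show", "ConicFit", function(object) {
  cat(sprintf("ConicFit [%s] subspace (%d,%d): R^2 = %.4f%s\n",
              object@mode, object@subspace[1], object@subspace[2], object@r2,
              if (object@degenerate) " (degenerate)" else ""))
})

setMethod("show", "CMCatalog", function(object) {
  cat("CMCatalog:", object@nFound, "CM(s) found\n")
  for (k in seq_along(object@cms))
    cat(sprintf("  CM_%d: {Psi_%d x Psi_%d}\n", k,
                object@cms[[k]][1], object@cms[[k]][2]))
  cat(" ", length(object@harmonics), "harmonic subspace(s) excluded\n")
})

setMethod("show", "RotationPlan", function(object) {
  cat("RotationPlan on d =", object@d, "eigenvectors:\n")
  if (nrow(object@ops) == 0) cat("  (identity)\n") else
    for (r in seq_len(nrow(object@ops)))
      cat(sprintf("  R_{%d,%d}(%g deg)\n", object@ops$i[r], object@ops$j[r],
                  object@ops$theta[r]))
})

setMethod("show", "BinSet", function(object) {
  cat("BinSet:", object@B, "equal-area bins;",
      sum(object@occupancy), "points assigned,",
      sum(object@outside), "outside the alpha polygon\n")
})

setMethod("show", "OccupancyMapND", function(object) {
  cat("OccupancyMapND:", paste(dim(object@counts), collapse = " x "),
      "cells, total", sum(object@counts), "assignments from",
      length(object@contributingPDs), "PD(s)\n")
})

setMethod("show", "EnergyLandscape", function(object) {
  v <- object@deltaG[object@mask]
  cat("EnergyLandscape:", paste(dim(object@deltaG), collapse = " x "),
      "bins; Delta G range [0,", sprintf("%.3f", max(v)), "] kT;",
      sum(!object@mask), "empty bin(s) masked\n")
})
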