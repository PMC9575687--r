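#' @include AllClasses.R partition.R
NULL

.spearman <- function(a, b) suppressWarnings(stats::cor(a, b, method = "spearman"))

#' Determine the global CM label and sense of each PD's motions
#'
#' The ordering direction of states along a CM trajectory is arbitrary per
#' PD (eigenfunction polarity is arbitrary), and so is the local CM
#' numbering, so both must be reconciled before compiling occupancies
#' across PDs. Mode `"ground_truth"` (synthetic data) matches each local
#' CM's bin index against every true state coordinate by maximal absolute
#' Spearman correlation; the sense is the correlation's sign. Mode
#' `"reference_pd"` takes the first gated PD as reference (labels and
#' senses as found) and matches the remaining PDs to it by maximal
#' absolute correlation of their per-bin occupancy profiles, flipped or
#' not. Matches whose top two candidate correlations lie within 0.05 are
#' flagged ambiguous.
#'
#' @param pdResults list of per-PD analysis records as produced by
#'   [analyzePD]: each a list with `pdId`, `binSets` (list of
#'   [BinSet-class] per local CM), `r2` (fit per local CM) and `meta`
#'   (image metadata with ground-truth `state*` columns when synthetic).
#' @param mode "ground_truth" or "reference_pd".
#' @param r2Min gate: PDs whose best CM fit is below this are skipped.
#' @return a [SenseMap-class].
#' @export
alignSenses <- function(pdResults, mode = c("ground_truth", "reference_pd"),
                        r2Min = 0.7) {
  mode <- match.arg(mode)
  gated <- Filter(function(p) length(p$r2) > 0 && max(p$r2) >= r2Min,
                  pdResults)
  if (!length(gated)) stop("no PD passes the R^2 gate")
  rows <- list()
  if (mode == "ground_truth") {
    for (p in gated) {
      stCols <- grep("^state[0-9]+$", names(p$meta), value = TRUE)
      if (!length(stCols))
        stop("ground_truth mode needs state* columns in the metadata")
      for (cm in seq_along(p$binSets)) {
        bins <- p$binSets[[cm]]@binOfImage
        cors <- vapply(stCols, function(sc) .spearman(bins, p$meta[[sc]]),
                       numeric(1))
        cors[is.na(cors)] <- 0
        ord <- order(abs(cors), decreasing = TRUE)
        amb <- length(cors) > 1 &&
          abs(cors[ord[1]]) - abs(cors[ord[2]]) < 0.05
        rows[[length(rows) + 1]] <- data.frame(
          pdId = p$pdId, cmLocal = cm, cmGlobal = ord[1],
          sense = ifelse(cors[ord[1]] >= 0, 1L, -1L),
          confidence = abs(cors[ord[1]]), ambiguous = amb)
      }
    }
  } else {
    ref <- gated[[1]]
    refOcc <- lapply(ref$binSets, function(b) b@occupancy)
    for (cm in seq_along(ref$binSets))
      rows[[length(rows) + 1]] <- data.frame(
        pdId = ref$pdId, cmLocal = cm, cmGlobal = cm, sense = 1L,
        confidence = 1, ambiguous = FALSE)
    for (p in gated[-1]) {
      for (cm in seq_along(p$binSets)) {
        occ <- p$binSets[[cm]]@occupancy
        sc <- vapply(refOcc, function(ro) {
          cf <- suppressWarnings(stats::cor(occ, ro))
          cr <- suppressWarnings(stats::cor(rev(occ), ro))
          cf[is.na(cf)] <- 0; cr[is.na(cr)] <- 0
          max(cf, cr)
        }, numeric(1))
        dirFlip <- vapply(refOcc, function(ro) {
          cf <- suppressWarnings(stats::cor(occ, ro))
          cr <- suppressWarnings(stats::cor(rev(occ), ro))
          cf[is.na(cf)] <- 0; cr[is.na(cr)] <- 0
          cr > cf
        }, logical(1))
        ord <- order(sc, decreasing = TRUE)
        amb <- length(sc) > 1 && sc[ord[1]] - sc[ord[2]] < 0.05
        rows[[length(rows) + 1]] <- data.frame(
          pdId = p$pdId, cmLocal = cm, cmGlobal = ord[1],
          sense = ifelse(dirFlip[ord[1]], -1L, 1L),
          confidence = sc[ord[1]], ambiguous = amb)
      }
    }
  }
  asn <- do.call(rbind, rows)
  rownames(asn) <- NULL
  if (any(asn$ambiguous))
    warning("ambiguous CM match for PD(s) ",
            paste(unique(asn$pdId[asn$ambiguous]), collapse = ", "),
            ": flagged for manual review")
  new("SenseMap", assignments = asn)
}

#' Intersect per-PD bin assignments into an n-D occupancy map
#'
#' Within one PD each image carries one (sense-corrected) bin index per
#' global CM; the image increments the count of the joint cell
#' (b_1, ..., b_n). Cells are aggregated over all PDs passing the R^2
#' gate. With a single CM no intersection is needed and the result is the
#' plain per-bin occupancy.
#'
#' @param pdResults per-PD records (see [alignSenses]).
#' @param senseMap a [SenseMap-class].
#' @param r2Min gate on the per-CM fit quality (default 0.7).
#' @param nCM number of global CMs (default: max label in the sense map).
#' @return an [OccupancyMapND-class].
#' @export
intersectIndices <- function(pdResults, senseMap, r2Min = 0.7, nCM = NULL) {
  asn <- senseMap@assignments
  if (is.null(nCM)) nCM <- max(asn$cmGlobal)
  B <- pdResults[[1]]$binSets[[1]]@B
  counts <- array(0L, dim = rep(B, nCM))
  contrib <- integer()
  for (p in pdResults) {
    rows <- asn[asn$pdId == p$pdId, , drop = FALSE]
    if (!nrow(rows)) next
    ## when surplus local CMs map to the same global label (spurious
    ## conic fits), keep the best-matching one per label
    rows <- rows[order(rows$cmGlobal, -rows$confidence), , drop = FALSE]
    rows <- rows[!duplicated(rows$cmGlobal), , drop = FALSE]
    if (!setequal(rows$cmGlobal, seq_len(nCM))) {
      message("PD ", p$pdId, " excluded: incomplete CM assignment")
      next
    }
    if (any(p$r2[rows$cmLocal] < r2Min)) {
      message("PD ", p$pdId, " excluded by the R^2 gate")
      next
    }
    N <- length(p$binSets[[1]]@binOfImage)
    cellIdx <- matrix(0L, N, nCM)
    for (r in seq_len(nrow(rows))) {
      bins <- p$binSets[[rows$cmLocal[r]]]@binOfImage
      if (rows$sense[r] < 0) bins <- B + 1L - bins
      cellIdx[, rows$cmGlobal[r]] <- bins
    }
    lin <- 1L + as.integer((cellIdx - 1L) %*% B^(seq_len(nCM) - 1L))
    tab <- tabulate(lin, nbins = B^nCM)
    counts <- counts + array(tab, dim = rep(B, nCM))
    contrib <- c(contrib, p$pdId)
  }
  if (!length(contrib)) stop("no PD contributed to the occupancy map")
  new("OccupancyMapND", counts = counts, contributingPDs = contrib,
      gate = r2Min)
}

#' Convert an occupancy map to a free-energy landscape
#'
#' Boltzmann statistics: the relative number of sightings of each state
#' gives its free energy, Delta G = -kT log(counts / max(counts)). Empty
#' cells are masked (no pseudo-count); the landscape is invariant under
#' global rescaling of the counts and its minimum over unmasked cells is
#' zero at the reference (max occupancy) bin.
#'
#' @param occ an [OccupancyMapND-class] (or a bare counts array).
#' @param kT thermal energy unit (default 1, i.e. landscapes in kT).
#' @return an [EnergyLandscape-class].
#' @export
occupancyToEnergy <- function(occ, kT = 1) {
  counts <- if (is(occ, "OccupancyMapND")) occ@counts else as.array(occ)
  if (all(counts == 0)) stop("occupancy map is all zero")
  mask <- counts > 0
  dG <- array(NA_real_, dim = dim(counts))
  mx <- max(counts)
  dG[mask] <- -kT * log(counts[mask] / mx)
  ref <- which(counts == mx, arr.ind = TRUE)
  ref <- as.integer(ref[1, ])
  new("EnergyLandscape", deltaG = dG, mask = mask, referenceBin = ref,
      kT = kT)
}

#' Export per-state image stacks and alignment tables
#'
#' For each selected cell of the n-D state space, collects the image
#' indices assigned to that cell in every contributing PD, and writes one
#' MRCS stack plus a STAR-style alignment table (orientation quaternion,
#' defocus, pixel size) per state, suitable as input for external 3D
#' reconstruction. Empty cells are skipped with a warning.
#'
#' @param pdResults per-PD records (see [alignSenses]).
#' @param senseMap a [SenseMap-class].
#' @param stacks named list of source [ImageStack-class] per PD (names
#'   "PD<id>" as produced by [assembleDataset]).
#' @param selection integer matrix of cells (one row per state, one column
#'   per CM).
#' @param outDir output directory.
#' @param r2Min gate for occupancy contribution; exported stacks include
#'   all PDs with assignments by default (gate 0).
#' @return a [StateStackManifest-class].
#' @export
exportStateStacks <- function(pdResults, senseMap, stacks, selection,
                              outDir, r2Min = 0) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  selection <- matrix(as.integer(selection), ncol = ncol(as.matrix(selection)))
  asn <- senseMap@assignments
  nCM <- max(asn$cmGlobal)
  B <- pdResults[[1]]$binSets[[1]]@B
  entries <- list(); idLists <- list()
  for (s in seq_len(nrow(selection))) {
    cell <- selection[s, ]
    label <- paste(sprintf("%02d", cell), collapse = "_")
    ids <- integer(); imgs <- list(); metaRows <- list()
    for (p in pdResults) {
      rows <- asn[asn$pdId == p$pdId, , drop = FALSE]
      if (!nrow(rows) || any(p$r2[rows$cmLocal] < r2Min)) next
      sel <- rep(TRUE, nrow(p$meta))
      for (r in seq_len(nrow(rows))) {
        bins <- p$binSets[[rows$cmLocal[r]]]@binOfImage
        if (rows$sense[r] < 0) bins <- B + 1L - bins
        sel <- sel & (bins == cell[rows$cmGlobal[r]])
      }
      if (!any(sel)) next
      stack <- stacks[[paste0("PD", p$pdId)]]
      ids <- c(ids, p$meta$imageId[sel])
      imgs[[length(imgs) + 1]] <- stack@images[, , sel, drop = FALSE]
      metaRows[[length(metaRows) + 1]] <- p$meta[sel, , drop = FALSE]
    }
    if (!length(ids)) {
      warning("state ", label, " is empty; skipped")
      next
    }
    allImgs <- array(unlist(imgs), c(dim(imgs[[1]])[1:2], length(ids)))
    meta <- do.call(rbind, metaRows)
    stackPath <- file.path(outDir, paste0("state_", label, ".mrcs"))
    alignPath <- file.path(outDir, paste0("state_", label, ".star"))
    px <- stacks[[1]]@pixelSizeA
    writeMRCS(new("ImageStack", images = allImgs, pixelSizeA = px,
                  meta = meta), stackPath)
    writeStarTable(cbind(meta, pixelSizeA = px), alignPath)
    entries[[length(entries) + 1]] <- data.frame(
      state = label, stackPath = stackPath, alignmentPath = alignPath,
      nImages = length(ids))
    idLists[[label]] <- ids
  }
  new("StateStackManifest",
      entries = if (length(entries)) do.call(rbind, entries) else
        data.frame(state = character(), stackPath = character(),
                   alignmentPath = character(), nImages = integer()),
      imageIds = idLists)
}
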