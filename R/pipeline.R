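#' @include AllClasses.R config.R embedding.R realign.R partition.R landscape.R
NULL

#' Analyze one PD image stack up to bin assignments
#'
#' Chains the per-PD half of the recovery workflow: spectral embedding
#' (diffusion maps by default, with the CTF double-filter distance when
#' defocus metadata is present and requested), CM subspace determination
#' with harmonic exclusion, eigenfunction realignment, and equal-area
#' partitioning of every CM subspace.
#'
#' @param stack an [ImageStack-class] of one PD.
#' @param method "DM" or "PCA".
#' @param doubleFilter use the CTF double-filter distances (requires
#'   defocus metadata and microscope params).
#' @param params a [MicroscopeParams-class] (double filter only).
#' @param d retained eigenvectors.
#' @param nMax,r2Min,constraint passed to [determineCMSubspaces].
#' @param operatorMode,histBins,thetaStep realignment controls.
#' @param B bins per CM.
#' @param quantileRange passed to [arccosTransform].
#' @param rescue when fewer than `nMax` CMs are found, additionally search
#'   rotation planes pairing each CM eigenvector with the unused
#'   eigenvectors; a candidate counter-rotation is kept only if
#'   re-determination then finds strictly more CM subspaces. This recovers
#'   motions whose parabolas are hidden below the R^2 gate by strong
#'   eigenfunction mixing.
#' @param preFilterSigma Gaussian band limit (pixels) applied by
#'   [lowpassStack] to a working copy of the stack before the distance
#'   computation; the default matches the generator's blob scale (the
#'   rendered signal carries no information beyond it, while white image
#'   noise does). Raw images are untouched downstream. Set 0 to disable.
#' @return per-PD record: list with `pdId`, `embedding` (realigned),
#'   `catalog`, `plan`, `fits`, `r2` (per CM), `binSets` (per CM),
#'   `meta`; or NULL fields downstream when no CM was found.
#' @export
analyzePD <- function(stack, method = "DM", doubleFilter = FALSE,
                      params = microscopeParams(), d = 15L, nMax = 3L,
                      r2Min = 0.7, constraint = "parabola",
                      operatorMode = "cross", histBins = 40L,
                      thetaStep = 1, B = 20L, quantileRange = c(0.02, 0.98),
                      rescue = TRUE, preFilterSigma = 1.5) {
  pdId <- imageMeta(stack)$pdId[1]
  if (is.na(pdId)) pdId <- 1L
  embStack <- lowpassStack(stack, preFilterSigma)
  emb <- if (method == "PCA") {
    pcaEmbed(embStack, d = d, pdId = pdId)
  } else {
    D <- if (doubleFilter) doubleFilterDistances(embStack, params)
         else pairwiseDistances(embStack)
    diffusionMap(D, d = d, pdId = pdId)
  }
  catalog <- determineCMSubspaces(emb, nMax = nMax, r2Min = r2Min,
                                  constraint = constraint)
  if (catalog@nFound > 0 && catalog@nFound < nMax && rescue) {
    res <- .rescueCMs(emb, catalog, nMax = nMax, r2Min = r2Min,
                      constraint = constraint, bins = histBins,
                      thetaGrid = seq(-90, 90 - thetaStep, by = thetaStep))
    emb <- res$embedding
    catalog <- res$catalog
  }
  rec <- list(pdId = as.integer(pdId), embedding = emb, catalog = catalog,
              plan = NULL, fits = list(), r2 = numeric(), binSets = list(),
              meta = imageMeta(stack))
  if (catalog@nFound == 0) return(rec)
  ra <- if (catalog@nFound >= 2) {
    realignEigenbasis(emb, catalog, mode = operatorMode, bins = histBins,
                      thetaGrid = seq(-90, 90 - thetaStep, by = thetaStep),
                      constraint = constraint)
  } else {
    list(embedding = emb,
         plan = new("RotationPlan",
                    ops = data.frame(i = integer(), j = integer(),
                                     theta = numeric()),
                    d = as.integer(ncol(eigVectors(emb)))),
         fits = lapply(cmSubspaces(catalog), function(s) {
           f <- fitConic(eigVectors(emb)[, s, drop = FALSE], constraint)
           f@subspace <- as.integer(s)
           f
         }))
  }
  rec$embedding <- ra$embedding
  rec$plan <- ra$plan
  rec$fits <- ra$fits
  rec$r2 <- vapply(ra$fits, function(f) f@r2, numeric(1))
  rec$binSets <- lapply(cmSubspaces(catalog), function(s)
    partitionSubspace(ra$embedding, s, B = B, quantileRange = quantileRange))
  rec
}

## Escape-hatch realignment: when strong mixing hides a CM parabola below
## the discovery gate, search planes pairing known-CM eigenvectors with
## unused ones; keep a counter-rotation only if the catalog then grows.
.rescueCMs <- function(emb, catalog, nMax, r2Min, constraint, bins,
                       thetaGrid) {
  for (pass in 1:2) {
    cmIdx <- unlist(cmSubspaces(catalog))
    ## mixing partners live among the leading eigenvectors; capping the
    ## search keeps the escape hatch inexpensive
    others <- setdiff(seq_len(min(ncol(eigVectors(emb)), 10L)), cmIdx)
    improved <- FALSE
    planes <- expand.grid(a = cmIdx, b = others)
    for (q in seq_len(nrow(planes))) {
      pl <- sort(c(planes$a[q], planes$b[q]))
      th <- histogramAngleSearch(emb, pl, thetaGrid, bins,
                                 subspaces = cmSubspaces(catalog))
      if (isTRUE(attr(th, "noRealignment")) || abs(th) < 2) next
      cand <- applyRotationPlan(emb, new("RotationPlan",
        ops = data.frame(i = pl[1], j = pl[2], theta = as.numeric(th)),
        d = as.integer(ncol(eigVectors(emb)))))
      candCat <- suppressMessages(
        determineCMSubspaces(cand, nMax = nMax, r2Min = r2Min,
                             constraint = constraint))
      if (candCat@nFound > catalog@nFound) {
        emb <- cand
        catalog <- candCat
        improved <- TRUE
        break
      }
    }
    if (!improved || catalog@nFound >= nMax) break
  }
  list(embedding = emb, catalog = catalog)
}

#' Run the full recovery pipeline from a configuration
#'
#' Simulates the synthetic continuum described by the config (or uses
#' supplied stacks), analyzes every PD, reconciles CM labels and senses,
#' intersects bin assignments into the n-D occupancy map and converts it
#' to a free-energy landscape. Fully reproducible from (config, seed): two
#' runs with the same config produce identical occupancy maps.
#'
#' @param config a [RunConfig-class].
#' @param stacks optional named list of [ImageStack-class] (skips
#'   simulation).
#' @return list with `stacks`, `pdResults`, `senseMap`, `occupancy`
#'   ([OccupancyMapND-class]), `energy` ([EnergyLandscape-class]),
#'   `log` (per-stage parameter/result records) and `config`.
#' @export
runPipeline <- function(config, stacks = NULL) {
  v <- config@values
  log <- list(configHash = config@hash)
  params <- microscopeParams(v$voltageKV, v$csMM, v$amplitudeContrast,
                             v$pixelSizeA, c(v$defocusMinUM, v$defocusMaxUM))
  if (is.null(stacks)) {
    model <- buildToyModel(v$preset, v$atomsPerDomain)
    ss <- generateStateSpace(model, n = v$n, M = v$M)
    pds <- fibonacciPDs(v$nPDs, v$apertureDeg)
    occSpec <- if (v$occupancyMode == "weighted") {
      w <- as.numeric(strsplit(v$weights, ",")[[1]])
      occupancySpec("weighted", tau = v$tau, weights = w)
    } else occupancySpec("uniform", tau = v$tau)
    stacks <- assembleDataset(model, ss, pds, occSpec,
                              datatype = v$datatype, params = params,
                              snr = v$snr, seed = v$seed, P = v$P,
                              blobSigma = v$blobSigma,
                              jitterOrientations = v$jitterOrientations)
    log$simulate <- list(nPDs = length(stacks),
                         imagesPerPD = nImages(stacks[[1]]),
                         datatype = v$datatype, snr = v$snr, seed = v$seed)
  }
  ctfData <- v$datatype >= 3
  doubleFilter <- if (is.na(v$doubleFilter)) ctfData else v$doubleFilter
  constraint <- if (is.na(v$constraint)) {
    if (ctfData) "general" else "parabola"
  } else v$constraint
  B <- if (is.na(v$B)) v$M else v$B
  qr <- if (is.na(v$quantileLo)) NULL else c(v$quantileLo, v$quantileHi)
  pdResults <- lapply(stacks, function(st)
    analyzePD(st, method = v$method, doubleFilter = doubleFilter,
              params = params, d = v$d, nMax = v$nMax, r2Min = v$r2Min,
              constraint = constraint, operatorMode = v$operatorMode,
              histBins = v$histBins, thetaStep = v$thetaStep, B = B,
              quantileRange = qr, preFilterSigma = v$preFilterSigma))
  log$perPD <- lapply(pdResults, function(p) list(
    pdId = p$pdId, nCM = p$catalog@nFound,
    subspaces = cmSubspaces(p$catalog), r2 = p$r2,
    rotations = if (is.null(p$plan)) NULL else p$plan@ops))
  senseMap <- alignSenses(pdResults, mode = v$senseMode, r2Min = v$r2Min)
  occupancy <- intersectIndices(pdResults, senseMap, r2Min = v$r2Min)
  energy <- occupancyToEnergy(occupancy, kT = v$kT)
  log$compile <- list(contributingPDs = occupancy@contributingPDs,
                      totalAssignments = sum(occupancy@counts))
  if (nzchar(v$outDir)) {
    dir.create(v$outDir, showWarnings = FALSE, recursive = TRUE)
    writeRunConfig(config, file.path(v$outDir, "run-config.txt"))
    utils::write.table(
      as.data.frame.table(occupancy@counts, responseName = "count"),
      file.path(v$outDir, "occupancy.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      as.data.frame.table(energy@deltaG, responseName = "deltaG_kT"),
      file.path(v$outDir, "energy.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(stacks = stacks, pdResults = pdResults, senseMap = senseMap,
       occupancy = occupancy, energy = energy, log = log, config = config)
}
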