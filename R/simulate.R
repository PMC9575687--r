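#' @include AllClasses.R geometry-utils.R toy-model.R
NULL

#' Construct microscope parameters
#'
#' Defaults are typical single-particle conditions: 300 kV, Cs 2.7 mm,
#' amplitude contrast 0.1, 1 Angstrom pixels, defocus 0.5-2.5 micrometer.
#'
#' @param voltageKV acceleration voltage (kV).
#' @param csMM spherical aberration (mm).
#' @param amplitudeContrast amplitude contrast fraction.
#' @param pixelSizeA pixel size (Angstrom).
#' @param defocusRangeUM c(min, max) defocus (micrometer, underfocus > 0).
#' @return a [MicroscopeParams-class].
#' @export
microscopeParams <- function(voltageKV = 300, csMM = 2.7,
                             amplitudeContrast = 0.1, pixelSizeA = 1.0,
                             defocusRangeUM = c(0.5, 2.5)) {
  new("MicroscopeParams", voltageKV = voltageKV, csMM = csMM,
      amplitudeContrast = amplitudeContrast, pixelSizeA = pixelSizeA,
      defocusRangeUM = defocusRangeUM)
}

#' Construct a per-state abundance specification
#'
#' @param mode "uniform" (tau copies per state) or "weighted" (counts
#'   proportional to nonnegative per-state weights).
#' @param tau integer copies per state; in weighted mode, the mean copies
#'   per state (total images = tau * number of states).
#' @param weights numeric per-state weights (weighted mode only).
#' @return an [OccupancySpec-class].
#' @export
occupancySpec <- function(mode = c("uniform", "weighted"), tau = 1L,
                          weights = numeric()) {
  mode <- match.arg(mode)
  new("OccupancySpec", mode = mode, tau = as.integer(tau),
      weights = as.numeric(weights))
}

#' Relativistic electron wavelength in Angstrom
#' @param voltageKV acceleration voltage in kV.
#' @export
electronWavelength <- function(voltageKV) {
  V <- voltageKV * 1e3
  12.2639 / sqrt(V + 0.97845e-6 * V^2)
}

#' Contrast transfer function on the image frequency grid
#'
#' CTF(k) = -(sqrt(1 - A^2) sin(chi) + A cos(chi)) with phase
#' chi(k) = pi lambda k^2 (df - lambda^2 Cs k^2 / 2); negative contrast at
#' low frequency (underfocus df > 0). No envelope unless `envelopeB > 0`,
#' in which case a Gaussian envelope exp(-B k^2 / 4) multiplies the CTF.
#'
#' @param P image side (even).
#' @param defocusUM defocus in micrometer.
#' @param params a [MicroscopeParams-class].
#' @param envelopeB optional B-factor (Angstrom^2) for a Gaussian envelope.
#' @return P x P matrix of CTF values arranged on the unshifted FFT grid.
#' @export
ctfGrid <- function(P, defocusUM, params, envelopeB = 0) {
  lambda <- electronWavelength(params@voltageKV)
  df <- defocusUM * 1e4          # um -> Angstrom
  cs <- params@csMM * 1e7        # mm -> Angstrom
  A <- params@amplitudeContrast
  f1 <- c(0:(P / 2 - 1), -(P / 2):-1) / (P * params@pixelSizeA)
  k2 <- outer(f1^2, f1^2, "+")
  chi <- pi * lambda * k2 * (df - 0.5 * lambda^2 * cs * k2)
  ctf <- -(sqrt(1 - A^2) * sin(chi) + A * cos(chi))
  if (envelopeB > 0) ctf <- ctf * exp(-envelopeB * k2 / 4)
  ctf
}

#' Apply a contrast transfer function to an image
#'
#' Multiplication in Fourier space; the CTF grid is real and even in k, so
#' the output is real (Hermitian symmetry preserved).
#'
#' @param image P x P matrix, P even.
#' @param defocusUM defocus in micrometer (negative = overfocus, allowed
#'   with a warning).
#' @param params a [MicroscopeParams-class].
#' @param envelopeB optional Gaussian envelope B-factor.
#' @return filtered P x P image.
#' @export
applyCTF <- function(image, defocusUM, params, envelopeB = 0) {
  P <- nrow(image)
  if (P %% 2 != 0) stop("image side must be even")
  if (defocusUM <= 0)
    warning("nonpositive defocus: interpreting as overfocus")
  ctf <- ctfGrid(P, defocusUM, params, envelopeB)
  Re(stats::fft(stats::fft(image) * ctf, inverse = TRUE)) / (P * P)
}

#' Add calibrated i.i.d. Gaussian noise to an image
#'
#' Noise variance is `signalVar / snr`, where `signalVar` is the pixel
#' variance of the clean signal; when simulating a whole PD the variance is
#' computed once over the clean ensemble so every image in a regime
#' receives noise of the same (constant) variance. Seeded and reproducible;
#' `snr = Inf` returns the image unchanged.
#'
#' @param image P x P matrix.
#' @param snr signal-to-noise ratio (> 0, or Inf for noiseless).
#' @param rngSeed integer seed for this image's noise draw.
#' @param signalVar pixel variance of the clean signal ensemble; defaults
#'   to the variance of `image` itself.
#' @return noisy image.
#' @export
addNoise <- function(image, snr, rngSeed, signalVar = stats::var(as.vector(image))) {
  if (is.infinite(snr)) return(image)
  if (snr <= 0) stop("snr must be positive")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rngSeed)
  image + matrix(stats::rnorm(length(image), sd = sqrt(signalVar / snr)),
                 nrow(image), ncol(image))
}

## per-state image counts under an occupancy spec (deterministic largest
## remainder in weighted mode)
.stateCounts <- function(occupancy, nStates) {
  if (occupancy@mode == "uniform") return(rep(occupancy@tau, nStates))
  if (length(occupancy@weights) != nStates)
    stop("need one weight per state (", nStates, ")")
  total <- occupancy@tau * nStates
  w <- occupancy@weights / sum(occupancy@weights)
  raw <- w * total
  cnt <- floor(raw)
  rem <- total - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}

#' Simulate per-PD projection image stacks for a state space
#'
#' Implements the four progressive realism tiers: data-type I (clean, one
#' image per state), II (+ per-state abundance tau and calibrated Gaussian
#' noise at a stated SNR), III (+ CTF with per-image random defocus), and
#' IV (+ nonuniform per-state occupancy). Every image carries full ground
#' truth in the stack metadata (state multi-index, defocus, noise seed,
#' per-image orientation quaternion).
#'
#' All randomness (defocus draws, noise, optional orientation jitter) flows
#' from `seed` through per-image derived seeds recorded in the metadata.
#'
#' @param model a [ToyModel-class].
#' @param stateSpace a [StateSpace-class].
#' @param pds a [ProjectionDirections-class].
#' @param occupancy an [OccupancySpec-class]; data-type I forces uniform
#'   tau = 1, data-type IV requires weighted mode.
#' @param datatype 1, 2, 3 or 4 (or "I".."IV").
#' @param params a [MicroscopeParams-class] (data-types III/IV).
#' @param snr signal-to-noise ratio (data-types II-IV; Inf = noiseless).
#' @param seed master integer seed.
#' @param P image side in pixels.
#' @param blobSigma Gaussian blob sigma in pixels.
#' @param jitterOrientations if TRUE, each image's orientation is jittered
#'   within the PD aperture (default FALSE: all images in a PD share the
#'   PD orientation exactly).
#' @return named list of [ImageStack-class], one per PD.
#' @export
assembleDataset <- function(model, stateSpace, pds,
                            occupancy = occupancySpec("uniform", 1L),
                            datatype = 1L, params = microscopeParams(),
                            snr = Inf, seed = 1L, P = 64L, blobSigma = 1.5,
                            jitterOrientations = FALSE) {
  dt <- if (is.character(datatype)) match(toupper(datatype),
                                          c("I", "II", "III", "IV"))
        else as.integer(datatype)
  if (is.na(dt) || !dt %in% 1:4) stop("datatype must be I..IV (1..4)")
  if (dt == 1 && !(occupancy@mode == "uniform" && occupancy@tau == 1L))
    stop("data-type I requires uniform occupancy with tau = 1")
  if (dt == 1 && is.finite(snr))
    stop("data-type I is noiseless; use datatype II to set an SNR")
  if (dt == 4 && occupancy@mode != "weighted")
    stop("data-type IV requires a weighted occupancy")
  if (dt %in% 2:3 && occupancy@mode != "uniform")
    stop("data-types II/III use uniform occupancy; use IV for weights")
  nStates <- nrow(stateSpace@states)
  counts <- .stateCounts(occupancy, nStates)
  useCTF <- dt >= 3
  out <- vector("list", length(pds@id))
  names(out) <- paste0("PD", pds@id)
  for (p in seq_along(pds@id)) {
    pdId <- pds@id[p]
    quat <- pds@quaternion[p, ]
    ## clean image per state (cached once per PD)
    clean <- array(0, c(P, P, nStates))
    for (s in seq_len(nStates))
      clean[, , s] <- renderProjection(model, stateSpace@angles[s, ], quat,
                                       P = P, blobSigma = blobSigma)
    N <- sum(counts)
    imgs <- array(0, c(P, P, N))
    stateRow <- rep(seq_len(nStates), counts)
    defocus <- rep(NA_real_, N)
    seeds <- integer(N)
    qmat <- matrix(rep(quat, each = N), N, 4)
    for (ii in seq_len(N)) {
      seeds[ii] <- deriveSeed(seed, pdId * 100000L + ii)
      if (jitterOrientations) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        set.seed(deriveSeed(seeds[ii], 3L))
        az <- stats::runif(1, 0, 2 * pi)
        tilt <- pds@apertureDeg / 2 * sqrt(stats::runif(1))
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
        dq <- quatFromAxisAngle(c(cos(az), sin(az), 0), tilt)
        qmat[ii, ] <- quatMultiply(dq, quat)
        imgs[, , ii] <- renderProjection(model, stateSpace@angles[stateRow[ii], ],
                                         qmat[ii, ], P = P, blobSigma = blobSigma)
      } else {
        imgs[, , ii] <- clean[, , stateRow[ii]]
      }
    }
    if (useCTF) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(deriveSeed(seed, pdId * 7L + 1L))
      defocus <- stats::runif(N, params@defocusRangeUM[1],
                              params@defocusRangeUM[2])
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      for (ii in seq_len(N))
        imgs[, , ii] <- applyCTF(imgs[, , ii], defocus[ii], params)
    }
    if (dt >= 2 && is.finite(snr)) {
      ## constant noise variance per PD per regime, from the clean
      ## (post-CTF when present) signal ensemble
      signalVar <- stats::var(as.vector(imgs))
      for (ii in seq_len(N))
        imgs[, , ii] <- addNoise(imgs[, , ii], snr, seeds[ii], signalVar)
    }
    meta <- data.frame(
      imageId = pdId * 1000000L + seq_len(N),
      pdId = pdId,
      stateSpace@states[stateRow, , drop = FALSE],
      defocusUM = defocus,
      snr = if (dt >= 2) snr else Inf,
      noiseSeed = seeds,
      q1 = qmat[, 1], q2 = qmat[, 2], q3 = qmat[, 3], q4 = qmat[, 4],
      row.names = NULL)
    out[[p]] <- new("ImageStack", images = imgs,
                    pixelSizeA = params@pixelSizeA, meta = meta)
  }
  out
}
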