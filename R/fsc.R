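#' @include AllClasses.R
NULL

#' Fourier shell correlation between two volumes
#'
#' Per-shell normalized cross-correlation of the Fourier coefficients of
#' two equally-shaped cubic volumes: shells are integer-radius bins of the
#' unshifted FFT grid, and shell s corresponds to spatial frequency
#' s / (G * pixelSize) (1/Angstrom).
#'
#' @param volA,volB cubic numeric arrays of equal shape.
#' @param pixelSizeA pixel size in Angstrom.
#' @return data.frame with columns `shell`, `freq` (1/Angstrom) and `fsc`.
#' @export
fsc <- function(volA, volB, pixelSizeA = 1) {
  if (!identical(dim(volA), dim(volB)))
    stop("volumes must have identical shapes")
  d <- dim(volA)
  if (length(d) != 3 || length(unique(d)) != 1)
    stop("volumes must be cubic")
  G <- d[1]
  FA <- stats::fft(volA)
  FB <- stats::fft(volB)
  f1 <- c(0:(ceiling(G / 2) - 1), -(floor(G / 2)):-1)
  r <- sqrt(outer(outer(f1^2, f1^2, "+"), f1^2, "+"))
  shell <- round(r)
  maxS <- floor(G / 2)
  keep <- shell <= maxS
  num <- Re(FA * Conj(FB))
  pa <- Mod(FA)^2
  pb <- Mod(FB)^2
  sNum <- tapply(num[keep], shell[keep], sum)
  sA <- tapply(pa[keep], shell[keep], sum)
  sB <- tapply(pb[keep], shell[keep], sum)
  den <- sqrt(sA * sB)
  val <- ifelse(den > 0, sNum / den, 0)
  s <- as.integer(names(sNum))
  data.frame(shell = s, freq = s / (G * pixelSizeA), fsc = as.numeric(val))
}

#' Resolution at an FSC threshold
#'
#' Returns 1 / frequency at the first crossing of the FSC curve below the
#' threshold, linearly interpolated between shells; the 0.143 threshold is
#' the conventional reproducible-resolution criterion. If the curve never
#' drops below the threshold the Nyquist resolution (2 * pixel size) is
#' returned with a warning.
#'
#' @param curve data.frame from [fsc].
#' @param threshold FSC threshold (default 0.143).
#' @return resolution in Angstrom.
#' @export
resolutionAt <- function(curve, threshold = 0.143) {
  cv <- curve[curve$shell > 0, , drop = FALSE]
  below <- which(cv$fsc < threshold)
  if (!length(below)) {
    warning("FSC never crosses the threshold; reporting Nyquist")
    return(1 / max(cv$freq))
  }
  k <- below[1]
  if (k == 1) return(1 / cv$freq[1])
  f0 <- cv$freq[k - 1]; f1 <- cv$freq[k]
  y0 <- cv$fsc[k - 1]; y1 <- cv$fsc[k]
  fx <- f0 + (threshold - y0) * (f1 - f0) / (y1 - y0)
  1 / fx
}
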