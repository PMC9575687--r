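#' @include AllClasses.R simulate.R
NULL

## N x P^2 pixel-vector matrix of a stack
.flattenStack <- function(stack) {
  d <- dim(stack@images)
  t(matrix(stack@images, d[1] * d[2], d[3]))
}

#' Gaussian low-pass filter an image stack
#'
#' Multiplies every image spectrum by `exp(-2 pi^2 sigma^2 k^2)`, the
#' transfer function of a Gaussian of width `sigma` pixels. The rendered
#' signal is itself band-limited to the pseudo-atom blob scale, so
#' filtering at that scale before computing pairwise distances removes
#' image-noise power from frequencies that carry no conformational signal
#' and sharply improves the spectral geometry at low SNR; the raw images
#' are kept untouched for movie frames and exported stacks.
#'
#' @param stack an [ImageStack-class].
#' @param sigma filter width in pixels (0 = no-op).
#' @return filtered [ImageStack-class].
#' @export
lowpassStack <- function(stack, sigma) {
  if (sigma <= 0) return(stack)
  P <- dim(stack@images)[1]
  f1 <- c(0:(P / 2 - 1), -(P / 2):-1) / P
  H <- exp(-2 * pi^2 * sigma^2 * outer(f1^2, f1^2, "+"))
  imgs <- stack@images
  for (i in seq_len(dim(imgs)[3]))
    imgs[, , i] <- Re(stats::fft(stats::fft(imgs[, , i]) * H,
                                 inverse = TRUE)) / P^2
  initialize(stack, images = imgs)
}

#' Euclidean pairwise distances between images of a stack
#'
#' @param stack an [ImageStack-class] (N >= 3 images).
#' @return a [DistanceMatrix-class] with method "plain".
#' @export
pairwiseDistances <- function(stack) {
  if (nImages(stack) < 3) stop("need at least 3 images")
  X <- .flattenStack(stack)
  if (any(!is.finite(X))) stop("non-finite pixels in stack")
  G <- tcrossprod(X)
  sq <- diag(G)
  D2 <- outer(sq, sq, "+") - 2 * G
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  new("DistanceMatrix", D = D, method = "plain")
}

#' CTF double-filter pairwise distances
#'
#' Distance between images i and j is the Euclidean norm of
#' `CTF_j * I_i - CTF_i * I_j` in Fourier space: each image is filtered by
#' the other image's CTF before differencing, which suppresses
#' CTF-induced manifold distortion. Symmetric by construction.
#'
#' @param stack an [ImageStack-class] whose metadata carries `defocusUM`.
#' @param params a [MicroscopeParams-class].
#' @param envelopeB optional Gaussian envelope B-factor.
#' @return a [DistanceMatrix-class] with method "double_filter".
#' @export
doubleFilterDistances <- function(stack, params, envelopeB = 0) {
  meta <- imageMeta(stack)
  if (is.null(meta$defocusUM) || anyNA(meta$defocusUM))
    stop("every image needs a defocus for the double-filter kernel")
  N <- nImages(stack)
  P <- dim(stack@images)[1]
  Fs <- matrix(0i, N, P * P)
  Cs <- matrix(0, N, P * P)
  for (i in seq_len(N)) {
    Fs[i, ] <- as.vector(stats::fft(stack@images[, , i])) / P  # unitary
    Cs[i, ] <- as.vector(ctfGrid(P, meta$defocusUM[i], params, envelopeB))
  }
  A <- Mod(Fs)^2
  B <- Cs^2
  T1 <- A %*% t(B)                       # sum_k |F_i|^2 C_j^2
  G <- Cs * Fs
  T3 <- Re(G %*% Conj(t(G)))             # sum_k C_i F_i conj(C_j F_j)
  D2 <- T1 + t(T1) - 2 * T3
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  new("DistanceMatrix", D = D, method = "double_filter")
}

#' Select the Gaussian kernel bandwidth from the distance matrix
#'
#' Scans the kernel sum S(eps) = sum_ij exp(-D_ij^2 / (2 eps)) over a
#' logarithmic grid of bandwidths. On the log-log curve, the bandwidth is
#' taken at the geometric midpoint of the contiguous region around the
#' maximal slope where the slope is at least 25 percent of its maximum
#' (the linear regime of the sigmoid). Deterministic; for very large
#' matrices a fixed-stride subsample of rows is used.
#'
#' @param D a [DistanceMatrix-class] or numeric matrix (N >= 10).
#' @param nGrid number of bandwidth grid points.
#' @param maxPoints subsample cap on the number of rows scanned.
#' @return selected bandwidth epsilon (same squared units as D).
#' @export
selectBandwidth <- function(D, nGrid = 120L, maxPoints = 1200L) {
  if (is(D, "DistanceMatrix")) D <- D@D
  if (nrow(D) < 10) stop("need at least 10 points")
  if (nrow(D) > maxPoints) {
    keep <- unique(round(seq(1, nrow(D), length.out = maxPoints)))
    D <- D[keep, keep]
  }
  d2 <- D[upper.tri(D)]^2
  pos <- d2[d2 > 0]
  if (!length(pos)) stop("degenerate all-zero distance matrix")
  le <- seq(log(min(pos)) - log(100), log(max(d2)) + log(100),
            length.out = nGrid)
  logS <- vapply(le, function(l) {
    ## include N diagonal terms (exp(0) = 1)
    log(2 * sum(exp(-d2 / (2 * exp(l)))) + nrow(D))
  }, numeric(1))
  slope <- diff(logS) / diff(le)
  k <- which.max(slope)
  thr <- 0.25 * slope[k]
  lo <- k; while (lo > 1 && slope[lo - 1] >= thr) lo <- lo - 1
  hi <- k; while (hi < length(slope) && slope[hi + 1] >= thr) hi <- hi + 1
  exp((le[lo] + le[hi + 1]) / 2)
}

## deterministic pseudo-random unit start vector (no RNG state touched)
.lanczosStart <- function(N) {
  v <- sin(seq_len(N) * 12.9898) * 43758.5453
  v <- v - floor(v) - 0.5
  v / sqrt(sum(v^2))
}

## top-k eigenpairs of a dense symmetric matrix by Lanczos with full
## reorthogonalization; deterministic
.lanczosTopK <- function(S, k, m = max(4L * k, 80L)) {
  N <- nrow(S)
  m <- min(m, N)
  Q <- matrix(0, N, m)
  alpha <- numeric(m); beta <- numeric(m)
  q <- .lanczosStart(N)
  for (j in seq_len(m)) {
    Q[, j] <- q
    w <- as.vector(S %*% q)
    alpha[j] <- sum(w * q)
    w <- w - alpha[j] * q - if (j > 1) beta[j - 1] * Q[, j - 1] else 0
    ## full reorthogonalization (twice for stability)
    w <- w - Q[, 1:j, drop = FALSE] %*% crossprod(Q[, 1:j, drop = FALSE], w)
    w <- w - Q[, 1:j, drop = FALSE] %*% crossprod(Q[, 1:j, drop = FALSE], w)
    beta[j] <- sqrt(sum(w^2))
    if (beta[j] < 1e-13) { m <- j; break }
    q <- w / beta[j]
  }
  Tm <- diag(alpha[1:m])
  if (m > 1) {
    idx <- cbind(1:(m - 1), 2:m)
    Tm[idx] <- beta[1:(m - 1)]
    Tm[idx[, 2:1, drop = FALSE]] <- beta[1:(m - 1)]
  }
  et <- eigen(Tm, symmetric = TRUE)
  vals <- et$values[seq_len(k)]
  vecs <- Q[, 1:m, drop = FALSE] %*% et$vectors[, seq_len(k), drop = FALSE]
  list(values = vals, vectors = vecs)
}

## fix eigenvector polarity: third moment nonnegative (fall back to the
## first sufficiently large entry when the third moment vanishes)
.fixSigns <- function(V) {
  for (j in seq_len(ncol(V))) {
    m3 <- mean(V[, j]^3)
    s <- if (abs(m3) > 1e-12) sign(m3) else {
      nz <- which(abs(V[, j]) > 1e-8)[1]
      if (is.na(nz)) 1 else sign(V[nz, j])
    }
    V[, j] <- V[, j] * s
  }
  V
}

#' Diffusion-map embedding of a PD manifold
#'
#' Gaussian kernel `K = exp(-D^2 / (2 eps))` with alpha = 1 density
#' normalization (the Laplace-Beltrami limit: `K <- K / (q q^T)` with q the
#' kernel row sums) followed by row-stochastic Markov normalization. The
#' eigenvectors of the symmetric conjugate operator are converted to right
#' eigenvectors of the Markov operator, the trivial constant mode is
#' dropped, columns are unit-normalized and sign-fixed (nonnegative third
#' moment). Eigenvalues of the Markov operator lie in [0, 1].
#'
#' @param D a [DistanceMatrix-class] or numeric distance matrix.
#' @param epsilon kernel bandwidth; defaults to [selectBandwidth].
#' @param d number of retained nontrivial eigenvectors.
#' @param pdId PD identifier stored in the embedding.
#' @param denseLimit above this N, a deterministic Lanczos solver computes
#'   only the leading eigenpairs instead of a full dense decomposition.
#' @return an [Embedding-class] with method "DM".
#' @export
diffusionMap <- function(D, epsilon = NULL, d = 15L, pdId = 1L,
                         denseLimit = 2000L) {
  if (is(D, "DistanceMatrix")) D <- D@D
  N <- nrow(D)
  if (d >= N) stop("d must be smaller than the number of images")
  if (is.null(epsilon)) epsilon <- selectBandwidth(D)
  if (epsilon <= 0) stop("epsilon must be positive")
  K <- exp(-D^2 / (2 * epsilon))
  q <- rowSums(K)
  iso <- which(q - 1 < 1e-12)   # off-diagonal kernel mass ~ 0
  if (length(iso))
    stop("disconnected kernel graph: isolated image(s) ",
         paste(utils::head(iso, 10), collapse = ", "))
  K <- K / outer(q, q)                    # alpha = 1 density normalization
  rs <- rowSums(K)
  S <- K / outer(sqrt(rs), sqrt(rs))      # symmetric conjugate of Markov op
  k <- d + 1L
  if (N <= denseLimit) {
    es <- eigen(S, symmetric = TRUE)
    vals <- es$values[seq_len(k)]
    vecs <- es$vectors[, seq_len(k), drop = FALSE]
  } else {
    es <- .lanczosTopK(S, k)
    vals <- es$values
    vecs <- es$vectors
  }
  vals <- pmin(pmax(vals, 0), 1)
  ## right eigenvectors of the Markov operator; drop the constant mode
  Psi <- vecs / sqrt(rs)
  Psi <- Psi[, -1, drop = FALSE]
  nrm <- sqrt(colSums(Psi^2))
  nrm[nrm < 1e-300] <- 1
  Psi <- sweep(Psi, 2, nrm, "/")
  Psi <- .fixSigns(Psi)
  degenerate <- vals[2] < 1e-12
  if (degenerate)
    warning("degenerate embedding: no nontrivial spectral gap ",
            "(all images identical?)")
  emb <- new("Embedding", eigvals = vals[-1], eigvecs = Psi,
             epsilon = epsilon, method = "DM", pdId = as.integer(pdId))
  attr(emb, "degenerate") <- degenerate
  emb
}

#' PCA embedding of a PD image stack
#'
#' Mean-centered principal component scores, unit-normalized per column and
#' sign-fixed like the diffusion-map eigenvectors. Eigenvalues are the
#' explained variances.
#'
#' @param stack an [ImageStack-class].
#' @param d number of components.
#' @param pdId PD identifier.
#' @return an [Embedding-class] with method "PCA".
#' @export
pcaEmbed <- function(stack, d = 15L, pdId = 1L) {
  X <- .flattenStack(stack)
  N <- nrow(X)
  if (d >= min(N, ncol(X))) stop("d must be < min(N, P^2)")
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X, nu = d, nv = 0)
  scores <- sv$u
  scores <- sweep(scores, 2, sqrt(colSums(scores^2)), "/")
  scores <- .fixSigns(scores)
  new("Embedding", eigvals = (sv$d[seq_len(d)]^2) / (N - 1),
      eigvecs = scores, epsilon = NA_real_, method = "PCA",
      pdId = as.integer(pdId))
}
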