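## Shared fixtures, all generated in code. Expensive simulated objects are
## memoized per test run.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixtureCache)) assign(name, builder(), .fixtureCache)
  get(name, .fixtureCache)
}

## midpoint conformational coordinate grid: the discrete Neumann Laplacian
## eigenvectors on an M-point path are cos(k pi (i + 1/2) / M)
xMid <- function(M) ((seq_len(M) - 1) + 0.5) / M

toyModel <- function() fixture("toy", function() buildToyModel("two_arm_v", 12L))

ss1Stacks <- function() fixture("ss1Stacks", function() {
  m <- toyModel()
  ss <- generateStateSpace(m, n = 1, M = 20)
  assembleDataset(m, ss, fibonacciPDs(4), datatype = 1)
})

ss1Embedding <- function() fixture("ss1Emb", function()
  diffusionMap(pairwiseDistances(ss1Stacks()[[1]]), d = 10))

ss2Stacks <- function() fixture("ss2Stacks", function() {
  m <- toyModel()
  ss <- generateStateSpace(m, n = 2, M = 20)
  assembleDataset(m, ss, fibonacciPDs(6), datatype = 1)
})

## analytic mixed eigenbasis on an M x M grid (canonical 2D Laplace
## eigenfunctions with two columns mixed by a planar rotation):
## column order psi1_x, psi2_x, psi1_y, psi2_y, psi3_x;
## CM subspaces at (1,2) and (3,4); mixing plane (2,3)
mixedEmbedding <- function(thetaDeg, M = 20, noiseSd = 0, seed = NULL) {
  g <- expand.grid(x = xMid(M), y = xMid(M))
  ps <- cbind(cos(pi * g$x), cos(2 * pi * g$x),
              cos(pi * g$y), cos(2 * pi * g$y), cos(3 * pi * g$x))
  t <- thetaDeg * pi / 180
  V <- ps
  V[, 2] <- cos(t) * ps[, 2] + sin(t) * ps[, 3]
  V[, 3] <- -sin(t) * ps[, 2] + cos(t) * ps[, 3]
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    V <- V + matrix(rnorm(length(V), sd = noiseSd), nrow(V))
  }
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  new("Embedding", eigvals = seq(0.9, 0.5, length.out = 5), eigvecs = V,
      epsilon = 1, method = "DM", pdId = 1L)
}

## small random image stack
randomStack <- function(N = 10, P = 16, seed = 1) {
  set.seed(seed)
  imgs <- array(rnorm(P * P * N), c(P, P, N))
  new("ImageStack", images = imgs, pixelSizeA = 1.0,
      meta = data.frame(imageId = seq_len(N), pdId = 1L,
                        defocusUM = seq(0.8, 2.2, length.out = N),
                        snr = Inf, noiseSeed = seq_len(N)))
}
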