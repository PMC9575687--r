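test_that("conic fits recover exact and noisy parabolas", {
  x <- seq(-1.5, 1.5, length.out = 25)
  f <- fitConic(cbind(x, x^2), "parabola")
  expect_equal(attr(f, "parabola"), c(1, 0, 0), tolerance = 1e-10)
  expect_equal(f@r2, 1)
  ## 20 points on the (cos, cos2) grid are exactly Chebyshev-parabolic
  xm <- xMid(20)
  f2 <- fitConic(cbind(cos(pi * xm), cos(2 * pi * xm)), "parabola")
  expect_gte(f2@r2, 0.999)
  expect_equal(attr(f2, "parabola"), c(2, 0, -1), tolerance = 1e-8)
  expect_error(fitConic(cbind(1:2, 1:2), "parabola"), "at least 3")
})

test_that("general conic fit matches the known ellipse coefficients", {
  th <- seq(0, 2 * pi, length.out = 40)[-40]
  a <- 2; b <- 1
  pts <- cbind(a * cos(th), b * sin(th))
  f <- fitConic(pts, "general")
  ## x^2/a^2 + y^2/b^2 - 1 = 0 in the fit's centered/scaled frame
  s <- stats::sd(c(pts[, 1], pts[, 2]))
  truth <- c(1 / a^2 * s^2, 0, 1 / b^2 * s^2, 0, 0, -1)
  truth <- truth / sqrt(sum(truth^2))
  cosSim <- abs(sum(f@coefficients * truth))
  expect_gte(cosSim, 0.999)
  expect_gte(f@r2, 0.99)
  ## collinear input flags a degenerate fit
  ln <- cbind(1:10, 2 * (1:10) + 1)
  fd <- fitConic(ln, "general")
  expect_true(fd@degenerate)
  expect_equal(fd@r2, 1)   # the line fit itself is perfect
})

test_that("rotation sub-matrix count is d(d-1)/2", {
  expect_equal(countRotationSubmatrices(5), 10)
  expect_equal(countRotationSubmatrices(4), 6)
  expect_equal(countRotationSubmatrices(2), 1)
  expect_error(countRotationSubmatrices(1), "d must be")
  for (d in 2:8)
    expect_equal(countRotationSubmatrices(d), nrow(t(combn(d, 2))))
})

test_that("CM determination finds the single continuum and its harmonics", {
  emb <- ss1Embedding()
  cat1 <- determineCMSubspaces(emb, nMax = 3)
  expect_equal(cat1@nFound, 1)
  expect_equal(cat1@cms[[1]], c(1L, 2L))
  ## index-sharing parabolas recorded as harmonics
  expect_true(any(vapply(cat1@harmonics, function(h) any(h %in% 1:2),
                         logical(1))))
  ## higher-order index-disjoint parabolas such as {Psi_3 x Psi_6} are
  ## rejected as repeats, never promoted to a second CM
  expect_true(list(c(3L, 6L)) %in% cat1@rejected ||
              any(vapply(cat1@rejected, function(r) identical(r, c(3L, 6L)),
                         logical(1))))
  expect_error(determineCMSubspaces(
    new("Embedding", eigvals = c(0.9, 0.5), eigvecs = cbind(rnorm(10), rnorm(10)),
        epsilon = 1, method = "DM", pdId = 1L)), "at least 4")
})

test_that("pure noise yields an empty catalog", {
  set.seed(8)
  st <- randomStack(N = 200, P = 16, seed = 8)
  emb <- diffusionMap(pairwiseDistances(st), d = 10)
  expect_message(cat0 <- determineCMSubspaces(emb, nMax = 2), "globular")
  expect_equal(cat0@nFound, 0)
})

test_that("two independent continua occupy index-disjoint subspaces", {
  st <- ss2Stacks()
  found <- 0
  for (pd in c(1, 3, 4)) {
    emb <- diffusionMap(pairwiseDistances(st[[pd]]), d = 15)
    cc <- suppressMessages(determineCMSubspaces(emb, nMax = 2))
    if (cc@nFound == 2) {
      found <- found + 1
      expect_length(intersect(cc@cms[[1]], cc@cms[[2]]), 0)
    }
  }
  expect_gte(found, 1)
})

test_that("essential operators pair CM subspaces", {
  mk <- function(cms) new("CMCatalog", cms = cms, harmonics = list(),
                          rejected = list(), fits = list(),
                          nFound = length(cms), r2Min = 0.7)
  expect_length(essentialOperators(mk(list(c(1L, 2L))), 10), 0)
  expect_length(essentialOperators(mk(list(c(1L, 3L), c(2L, 5L))), 10), 1)
  expect_length(essentialOperators(mk(list(c(1L, 2L), c(3L, 4L),
                                           c(5L, 6L))), 10), 3)
  expect_length(essentialOperators(mk(list(c(1L, 3L), c(2L, 5L))), 10,
                                   mode = "cross"), 4)
})

test_that("histogram angle search recovers analytic mixing angles", {
  subs <- list(c(1L, 2L), c(3L, 4L))
  for (th in c(10, 20, 35)) {
    emb <- mixedEmbedding(th)
    got <- histogramAngleSearch(emb, c(2, 3), subspaces = subs)
    expect_lte(abs(got - th), 2)
  }
  ## SNR-perturbed eigenvectors, three seeds
  for (s in 1:3) {
    emb <- mixedEmbedding(35, noiseSd = 0.008, seed = s)
    got <- histogramAngleSearch(emb, c(2, 3), subspaces = subs)
    expect_lte(abs(got - 35), 5)
  }
  ## already-aligned data needs no rotation
  emb0 <- mixedEmbedding(0)
  got0 <- histogramAngleSearch(emb0, c(2, 3), subspaces = subs)
  expect_lte(abs(got0), 1)
  ## symmetry: searching data pre-rotated by -theta* returns ~0
  emb <- mixedEmbedding(20)
  fixed <- applyRotationPlan(emb, new("RotationPlan",
    ops = data.frame(i = 2L, j = 3L, theta = 20), d = 5L))
  expect_lte(abs(histogramAngleSearch(fixed, c(2, 3), subspaces = subs)), 1)
})

test_that("rotation plans are orthogonal, invertible and column-local", {
  emb <- mixedEmbedding(25)
  plan <- new("RotationPlan",
              ops = data.frame(i = c(2L, 1L), j = c(3L, 4L),
                               theta = c(25, -40)), d = 5L)
  rot <- applyRotationPlan(emb, plan)
  ## column norms preserved
  expect_equal(colSums(eigVectors(rot)^2), colSums(eigVectors(emb)^2),
               tolerance = 1e-9)
  ## untouched columns unchanged
  expect_equal(eigVectors(rot)[, 5], eigVectors(emb)[, 5])
  ## plan composed with its inverse is the identity
  back <- applyRotationPlan(rot, invertPlan(plan))
  expect_equal(eigVectors(back), eigVectors(emb), tolerance = 1e-9)
  ## empty plan is the identity
  ep <- new("RotationPlan", ops = data.frame(i = integer(), j = integer(),
                                             theta = numeric()), d = 5L)
  expect_equal(eigVectors(applyRotationPlan(emb, ep)), eigVectors(emb))
  ## the composed operator O is orthogonal
  O <- diag(5)
  for (r in 1:2) {
    R <- diag(5)
    i <- plan@ops$i[r]; j <- plan@ops$j[r]; t <- plan@ops$theta[r] * pi / 180
    R[i, i] <- cos(t); R[j, j] <- cos(t)
    R[i, j] <- -sin(t); R[j, i] <- sin(t)
    O <- R %*% O
  }
  expect_lt(max(abs(O %*% t(O) - diag(5))), 1e-10)
})

test_that("realignment separates mixed eigenfunctions", {
  emb <- mixedEmbedding(20)
  catalog <- new("CMCatalog", cms = list(c(1L, 2L), c(3L, 4L)),
                 harmonics = list(), rejected = list(), fits = list(),
                 nFound = 2L, r2Min = 0.7)
  res <- realignEigenbasis(emb, catalog)
  r2 <- vapply(res$fits, function(f) f@r2, numeric(1))
  expect_true(all(r2 >= 0.99))
  expect_true(any(abs(res$plan@ops$theta - 20) <= 2))
  ## aligned embedding comes back unchanged with a zero plan
  emb0 <- mixedEmbedding(0)
  res0 <- realignEigenbasis(emb0, catalog)
  expect_equal(nrow(res0$plan@ops), 0)
  expect_equal(eigVectors(res0$embedding), eigVectors(emb0))
  ## noisy mixtures: post-rotation fits never drop, three seeds
  for (s in 1:3) {
    embN <- mixedEmbedding(20, noiseSd = 0.008, seed = s)
    pre <- vapply(catalog@cms, function(ss)
      fitConic(eigVectors(embN)[, ss])@r2, numeric(1))
    resN <- suppressWarnings(realignEigenbasis(embN, catalog))
    post <- vapply(resN$fits, function(f) f@r2, numeric(1))
    expect_true(all(post >= pre - 0.01))
    expect_gte(mean(post), mean(pre))
  }
})
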