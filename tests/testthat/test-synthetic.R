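test_that("toy model presets build valid machines", {
  m <- toyModel()
  expect_s4_class(m, "ToyModel")
  expect_length(m@hinges, 2)           # two mobile arm domains + core
  expect_true(any(m@domain == 0))
  ## hinge axes are unit vectors
  for (h in m@hinges)
    if (h$mode == "hinge") expect_equal(sqrt(sum(h$axis^2)), 1)
  ## zero-angle state leaves the seed coordinates untouched
  expect_equal(stateCoordinates(m, c(0, 0)), m@atoms)
  expect_error(buildToyModel("no_such_preset"), "unknown preset")
  expect_error(buildToyModel("two_arm_v", 2), "atomsPerDomain")
})

test_that("mouth_wings motion is a non-rigid displacement field", {
  m <- buildToyModel("mouth_wings", 12)
  c0 <- stateCoordinates(m, c(0, 0))
  c1 <- stateCoordinates(m, c(1, 0))
  mouth <- m@domain == 1
  d0 <- dist(c0[mouth, ])
  d1 <- dist(c1[mouth, ])
  ## inter-atom distances within the mouth change: not a rigid motion
  expect_gt(max(abs(d0 - d1)), 1)
  ## wings untouched when only the mouth moves
  expect_equal(c1[m@domain == 2, ], c0[m@domain == 2, ])
})

test_that("state spaces enumerate M^n equispaced states", {
  m <- toyModel()
  expect_equal(nrow(generateStateSpace(m, 2, 20)@states), 400)
  expect_equal(nrow(generateStateSpace(m, 1, 20)@states), 20)
  ss <- generateStateSpace(m, 1, 2)
  expect_equal(as.numeric(ss@angles[, 1]), m@hinges[[1]]$range)
  ss3 <- generateStateSpace(m, 2, 5)
  ang <- sort(unique(ss3@angles[, 1]))
  expect_equal(diff(ang), rep(10, 4))  # range 0..40 in 5 equispaced steps
  expect_error(generateStateSpace(m, 3, 20), "mobile domains")
})

test_that("rendered density is a sum of unit-integral blobs", {
  m <- toyModel()
  vol <- renderDensity(m, c(0, 0), gridSize = 64, blobSigma = 1.5)
  expect_true(all(vol >= 0))
  ## one unit of integral per pseudo-atom
  expect_equal(sum(vol), nrow(m@atoms), tolerance = 1e-3)
  ## linearity: the density of the full model is the sum over domains
  partial <- array(0, dim(vol))
  for (d in 0:2) {
    sub <- new("ToyModel",
               atoms = m@atoms[m@domain == d, ], domain = rep(0L, sum(m@domain == d)),
               hinges = list(), preset = "two_arm_v")
    partial <- partial + renderDensity(sub, numeric(), 64, 1.5)
  }
  expect_equal(vol, partial, tolerance = 1e-8)
  expect_error(renderDensity(m, c(0, 0), gridSize = 24), "outside")
})

test_that("projection conserves mass and matches the analytic renderer", {
  m <- toyModel()
  vol <- renderDensity(m, c(20, 10), gridSize = 64)
  ## identity orientation: plain sum along z
  expect_equal(projectVolume(vol), rowSums(vol, dims = 2))
  pds <- fibonacciPDs(5)
  for (p in c(2, 4)) {
    img <- projectVolume(vol, pds@quaternion[p, ])
    expect_equal(sum(img), sum(vol), tolerance = 1e-3)
    ## volume-resampling path agrees with the exact 2D Gaussian path
    ana <- renderProjection(m, c(20, 10), pds@quaternion[p, ])
    expect_lt(sqrt(mean((img - ana)^2)) / max(ana), 0.05)
  }
  expect_error(projectVolume(array(0, c(4, 4, 5))), "cubic")
})

test_that("in-plane motion displaces projections more than axial viewing", {
  m <- toyModel()
  ## arm 1 rotates about +z, so a small step displaces atoms along
  ## roughly (1,1,0)/sqrt(2); that motion is fully visible from the +z
  ## view and nearly invisible when viewing along the displacement
  top <- c(1, 0, 0, 0)
  v <- c(1, 1, 0) / sqrt(2)
  ax <- c(v[2], -v[1], 0)              # v x z
  ang <- atan2(sqrt(sum(ax^2)), v[3]) * 180 / pi
  alongDisp <- manifoldCM:::quatFromAxisAngle(ax, ang)
  stepL2 <- function(q) {
    i0 <- renderProjection(m, c(0, 0), q)
    i1 <- renderProjection(m, c(4, 0), q)
    sqrt(sum((i1 - i0)^2))
  }
  expect_gt(stepL2(top), 5 * stepL2(alongDisp))
})

test_that("CTF matches its closed form and composes multiplicatively", {
  params <- microscopeParams()
  P <- 64
  ctf <- ctfGrid(P, 1.5, params)
  expect_equal(ctf[1, 1], -params@amplitudeContrast)   # k = 0
  ## first zero crossing against a brute-force scan of the analytic curve
  lambda <- electronWavelength(300)
  chi <- function(k) pi * lambda * k^2 * (1.5e4 - 0.5 * lambda^2 * 2.7e7 * k^2)
  f <- function(k) -(sqrt(1 - 0.1^2) * sin(chi(k)) + 0.1 * cos(chi(k)))
  ks <- seq(1e-4, 0.5, by = 1e-5)
  v <- f(ks)
  kZero <- ks[which(v[-1] * v[-length(v)] < 0)[1]]
  kGrid <- c(0:(P / 2 - 1), -(P / 2):-1) / P
  rowCtf <- ctf[, 1]
  sgn <- sign(rowCtf[order(abs(kGrid))])
  kAxis <- sort(abs(kGrid))
  kZeroGrid <- kAxis[which(sgn[-1] * sgn[-length(sgn)] < 0)[1]]
  expect_lt(abs(kZeroGrid - kZero), 1.5 / P)
  ## applying the same CTF twice equals one multiplication by CTF^2
  img <- renderProjection(toyModel(), c(10, 30))
  twice <- applyCTF(applyCTF(img, 1.5, params), 1.5, params)
  sq <- Re(stats::fft(stats::fft(img) * ctf^2, inverse = TRUE)) / P^2
  expect_equal(twice, sq, tolerance = 1e-10)
  expect_warning(applyCTF(img, -0.5, params), "overfocus")
})

test_that("noise is calibrated, seeded and reproducible", {
  img <- renderProjection(toyModel(), c(20, 0))
  expect_identical(addNoise(img, Inf, 1), img)
  expect_error(addNoise(img, -1, 1), "positive")
  expect_identical(addNoise(img, 0.5, 42), addNoise(img, 0.5, 42))
  expect_false(identical(addNoise(img, 0.5, 42), addNoise(img, 0.5, 43)))
  ## Monte-Carlo check of the SNR definition at N = 400 draws
  sv <- var(as.vector(img))
  resid <- vapply(1:400, function(s)
    as.vector(addNoise(img, 0.1, s, sv) - img), numeric(length(img)))
  expect_equal(var(as.vector(resid)) * 0.1 / sv, 1, tolerance = 0.05)
})

test_that("assembleDataset builds the four data-type tiers", {
  m <- toyModel()
  ss1 <- generateStateSpace(m, 1, 20)
  pds <- fibonacciPDs(2)
  st <- assembleDataset(m, ss1, pds, datatype = 1)
  expect_length(st, 2)
  expect_equal(nImages(st[[1]]), 20)
  ## data-type I is deterministic and bit-reproducible
  st2 <- assembleDataset(m, ss1, pds, datatype = 1)
  expect_identical(st[[1]]@images, st2[[1]]@images)
  ## ordered noiseless sequence moves monotonically through image space
  steps <- vapply(1:19, function(i)
    sqrt(sum((st[[1]]@images[, , i + 1] - st[[1]]@images[, , i])^2)),
    numeric(1))
  expect_true(all(steps > 0))
  ## invalid combinations are configuration errors
  expect_error(assembleDataset(m, ss1, pds, occupancySpec("uniform", 5L),
                               datatype = 1), "tau = 1")
  expect_error(assembleDataset(m, ss1, pds, datatype = 1, snr = 0.5),
               "noiseless")
  expect_error(assembleDataset(m, ss1, pds, datatype = 4), "weighted")
  ## weighted mode with all weight on one state
  w <- c(rep(0, 7), 1, rep(0, 12))
  stw <- assembleDataset(m, ss1, fibonacciPDs(1),
                         occupancySpec("weighted", 2L, w), datatype = 4,
                         snr = 1, seed = 5)
  expect_equal(nImages(stw[[1]]), 40)
  expect_true(all(stw[[1]]@meta$state1 == 7))
  expect_true(all(is.finite(stw[[1]]@meta$defocusUM)))
})

test_that("per-PD noise has constant variance and meta stays consistent", {
  m <- toyModel()
  ss1 <- generateStateSpace(m, 1, 10)
  st <- assembleDataset(m, ss1, fibonacciPDs(1),
                        occupancySpec("uniform", 40L), datatype = 2,
                        snr = 0.2, seed = 11)
  s1 <- st[[1]]
  expect_equal(nImages(s1), 400)
  expect_equal(nrow(imageMeta(s1)), 400)
  expect_false(anyDuplicated(imageMeta(s1)$imageId) > 0)
  ## measured SNR within 5% of requested (clean ensemble reconstructable)
  clean <- assembleDataset(m, ss1, fibonacciPDs(1),
                           occupancySpec("uniform", 40L), datatype = 2,
                           snr = Inf, seed = 11)[[1]]
  noise <- s1@images - clean@images
  expect_equal(var(as.vector(clean@images)) / var(as.vector(noise)), 0.2,
               tolerance = 0.05 * 0.2 * 10)  # 5% on the SNR scale
  expect_equal(var(as.vector(clean@images)) / var(as.vector(noise)) / 0.2,
               1, tolerance = 0.05)
})
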