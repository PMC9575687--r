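test_that("arccos transform uniformizes cosine-sampled coordinates", {
  x <- runif(400)
  set.seed(5)
  phi <- arccosTransform(cos(pi * sort(runif(400))))
  ## Phi/pi is uniform on [0, 1]
  ks <- suppressWarnings(ks.test(phi / pi, "punif"))
  expect_lte(unname(ks$statistic), 0.05)
  ## endpoints map to 0 and pi (monotone decreasing)
  v <- cos(pi * xMid(20))
  p <- arccosTransform(v)
  expect_equal(p[which.max(v)], 0)
  expect_equal(p[which.min(v)], pi)
  expect_true(all(diff(p) > 0))   # v decreasing => Phi increasing
  ## spacing uniformity on the endpoint cosine grid (arccos-cos identity)
  v2 <- cos(pi * seq(0, 1, length.out = 20))
  p2 <- arccosTransform(v2)
  expect_lte(var(diff(p2)) / var(diff(v2)), 0.01)
  expect_error(arccosTransform(rep(1, 10)), "constant")
})

test_that("alpha shapes capture concavity and reduce to the hull", {
  set.seed(11)
  sq <- cbind(runif(3000), runif(3000))
  poly <- alphaShapePolygon(sq)
  expect_equal(abs(polygonArea(poly)), 1, tolerance = 0.05)
  ## alpha = 0 is the convex hull (on a cloud below the subsample cap)
  sq2 <- sq[1:1200, ]
  h <- alphaShapePolygon(sq2, alpha = 0)
  hull <- sq2[grDevices::chull(sq2), ]
  ## equal to the hull up to degenerate (collinear) boundary slivers
  expect_equal(abs(polygonArea(h)), abs(polygonArea(hull)), tolerance = 1e-3)
  ## crescent: concavity captured, area below the hull area
  th <- runif(1200, 0, pi)
  r <- runif(1200, 0.7, 1)
  cres <- cbind(r * cos(th), r * sin(th))
  pc <- alphaShapePolygon(cres)
  hullA <- abs(polygonArea(cres[grDevices::chull(cres), ]))
  expect_lt(abs(polygonArea(pc)), 0.8 * hullA)
  expect_gte(mean(pointInPolygon(cres, pc)), 0.99)
})

test_that("anchor sits on the symmetry axis outside the polygon", {
  set.seed(2)
  ## symmetric V-shaped cloud
  s <- runif(1500, -1, 1)
  v <- cbind(s, 2 * abs(s) + 0.05 * rnorm(1500))
  poly <- alphaShapePolygon(v)
  anchor <- placeAnchor(poly, v)
  fit <- attr(anchor, "absFit")
  expect_lt(abs(anchor[1] - fit[["h"]]), 1e-9)
  expect_lt(abs(fit[["h"]]), 0.1)
  expect_false(pointInPolygon(matrix(anchor, ncol = 2), poly))
  ## anchor is on the apex side, away from the arm opening
  expect_lt(anchor[2], fit[["k"]])
  ## vertically flipped cloud flips the anchor side
  vf <- cbind(v[, 1], -v[, 2])
  polyF <- alphaShapePolygon(vf)
  anchorF <- placeAnchor(polyF, vf)
  expect_gt(anchorF[2], -fit[["k"]] - 0.2)
  expect_gt(anchorF[2], attr(anchorF, "absFit")[["k"]])
})

test_that("equal-area bins conserve and equalize area", {
  ## half-disc with anchor just below the flat side: two quarter-discs
  th <- seq(0, pi, length.out = 200)
  hd <- rbind(cbind(cos(th), sin(th)))
  anchor <- c(0, -1e-3)
  bins <- equalAreaBins(hd, anchor, 2)
  expect_equal(bins$areas[1], bins$areas[2], tolerance = 1e-3 * pi / 2)
  expect_equal(sum(bins$areas), abs(polygonArea(hd)), tolerance = 1e-3)
  ## arbitrary polygon: areas sum to the whole and deviate < 1%
  set.seed(4)
  s <- runif(1200, -1, 1)
  v <- cbind(s, 1.5 * abs(s) + 0.3 * runif(1200))
  poly <- alphaShapePolygon(v)
  anchor2 <- placeAnchor(poly, v)
  b10 <- equalAreaBins(poly, anchor2, 10)
  A <- abs(polygonArea(poly))
  expect_equal(sum(b10$areas), A, tolerance = 1e-3 * A)
  expect_lt(max(abs(b10$areas - A / 10)), 0.01 * A / 10)
  ## the 50% cumulative-area boundary is the bin 5 / bin 6 cut
  bs <- assignBins(v, b10, poly)
  expect_equal(sum(bs@occupancy), nrow(v))
})

test_that("bin assignment conserves points and flags outsiders", {
  th <- seq(0, pi, length.out = 100)
  hd <- cbind(cos(th), sin(th))
  anchor <- c(0, -1e-3)
  bins <- equalAreaBins(hd, anchor, 4)
  ## single point at a bin centroid lands in that bin
  for (b in c(1, 3)) {
    ctr <- colMeans(bins$subPolygons[[b]])
    bs <- assignBins(rbind(ctr), bins, hd)
    expect_equal(bs@binOfImage, b)
  }
  ## outside point: flagged and assigned to the nearest bin
  bsOut <- assignBins(rbind(c(1.4, 0.1), colMeans(bins$subPolygons[[2]])),
                      bins, hd)
  expect_true(bsOut@outside[1])
  expect_false(bsOut@outside[2])
  expect_equal(sum(bsOut@occupancy), 2)
  ## sense reversal reverses the occupancy vector exactly
  set.seed(6)
  pts <- cbind(runif(500, -0.8, 0.8), runif(500, 0.1, 0.9))
  keep <- pointInPolygon(pts, hd)
  bs1 <- assignBins(pts[keep, ], bins, hd)
  rev1 <- 4 + 1 - bs1@binOfImage
  expect_equal(tabulate(rev1, 4), rev(bs1@occupancy))
})

test_that("partitioned noiseless continuum orders bins along ground truth", {
  st <- ss1Stacks()[[1]]
  emb <- ss1Embedding()
  bs <- partitionSubspace(emb, c(1L, 2L), B = 20)
  expect_equal(sum(bs@occupancy), 20)
  ## ordering follows the true conformational coordinate
  expect_gte(abs(cor(bs@binOfImage, imageMeta(st)$state1,
                     method = "spearman")), 0.99)
  ## equal-area within 1%
  areas <- vapply(bs@subPolygons, function(p) abs(polygonArea(p)), numeric(1))
  expect_lt(max(abs(areas - mean(areas))), 0.01 * mean(areas))
  ## near-lossless: every bin holds at most tau + 1 images
  expect_lte(max(bs@occupancy), 2)
})

test_that("movies average exactly the images of each bin", {
  st <- ss1Stacks()[[1]]
  truthBins <- imageMeta(st)$state1 + 1L
  mv <- makeMovie(st, truthBins, 20)
  ## noiseless lossless grouping: frame b is the clean state image
  for (b in c(1, 7, 20))
    expect_equal(mv@frames[, , b], st@images[, , b], tolerance = 1e-6)
  ## identical images give identical frames
  stI <- st; for (i in 1:20) stI@images[, , i] <- st@images[, , 1]
  mvI <- makeMovie(stI, truthBins, 20)
  for (b in c(2, 19)) expect_equal(mvI@frames[, , b], st@images[, , 1])
  ## even pace: frame-to-frame differences positive and comparable
  d <- vapply(1:19, function(b)
    sqrt(sum((mv@frames[, , b + 1] - mv@frames[, , b])^2)), numeric(1))
  expect_true(all(d > 0))
  expect_lte(max(d) / min(d), 3)
  ## empty bin flagged as zero frame
  expect_warning(mvE <- makeMovie(st, c(truthBins[-1], NA), 21), "empty")
  expect_true(any(mvE@empty))
})

test_that("SVD filtering reconstructs and denoises movies", {
  st <- ss1Stacks()[[1]]
  mv <- makeMovie(st, imageMeta(st)$state1 + 1L, 20)
  ## full rank: identity
  expect_equal(svdFilterMovie(mv, 20)@frames, mv@frames, tolerance = 1e-9)
  ## rank-1 movie recovered exactly from k = 1
  tmpl <- mv@frames[, , 1]
  r1 <- mv
  for (b in 1:20) r1@frames[, , b] <- b * tmpl
  expect_equal(svdFilterMovie(r1, 1)@frames, r1@frames, tolerance = 1e-8)
  ## noisy frames: per-frame correlation to clean improves after k = 3
  set.seed(12)
  noisy <- mv
  noisy@frames <- mv@frames + array(rnorm(length(mv@frames),
                                          sd = 2 * sd(mv@frames)),
                                    dim(mv@frames))
  filt <- svdFilterMovie(noisy, 3)
  corTo <- function(a) vapply(1:20, function(b)
    cor(as.vector(a@frames[, , b]), as.vector(mv@frames[, , b])), numeric(1))
  expect_gt(mean(corTo(filt)), mean(corTo(noisy)))
  expect_error(svdFilterMovie(mv, 100), "k must be")
})
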