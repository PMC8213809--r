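test_that("ellipse fit is exact on noise-free rings and ellipses", {
  ang <- 2 * pi * (0:7) / 8
  circ <- LocalizationSet(80 * cbind(cos(ang), sin(ang)), sigma = 1)
  f <- fitEllipseToRing(circ, nSites = 8)
  expect_equal(ellipticity(f), 1, tolerance = 1e-6)

  # parametric ellipse with a/b = 1.3, rotated and shifted
  th <- 0.6
  a <- 80 * sqrt(1.3)
  b <- 80 / sqrt(1.3)
  R <- rotationMatrix2D(th)
  pts <- t(R %*% rbind(a * cos(ang + 0.2), b * sin(ang + 0.2))) +
    matrix(c(15, -40), 8, 2, byrow = TRUE)
  fe <- fitEllipseDirect(pts)
  expect_equal(ellipticity(fe), 1.3, tolerance = 1e-6)
  expect_equal(fe@a, a, tolerance = 1e-6)
  expect_equal(fe@b, b, tolerance = 1e-6)
  expect_equal(fe@center, c(15, -40), tolerance = 1e-6)
  # orientation recovered modulo pi
  expect_lt(min(abs(fe@theta - th), pi - abs(fe@theta - th)), 1e-6)
  expect_error(fitEllipseDirect(cbind(1:8, 2 * (1:8))), "degenerate|collinear")
})

test_that("ellipticity is invariant under rigid motion", {
  set.seed(71)
  tpl <- makeTemplate("ring", nFold = 8, diameter = 160)
  p <- sampleParticle(tpl, acquisitionModel(dol = 1, locsPerSite = 30,
                                            sigmaMeanNm = 2),
                      deformation = 1.2)
  f1 <- fitEllipseToRing(p, nSites = 8)
  tr <- rigidTransform(theta = 1.1, t = c(50, -20))
  p2 <- LocalizationSet(applyTransform(tr, coords(p)), sigmas(p))
  f2 <- fitEllipseToRing(p2, nSites = 8)
  # blob partition and arc seeds are rotation-invariant; the residual
  # variation comes from the coordinate-wise median, which is only
  # approximately equivariant at finite blob size
  expect_equal(ellipticity(f2), ellipticity(f1), tolerance = 0.02)
  expect_gt(ellipticity(f1), 1.1)  # deformation visible
  expect_lt(ellipticity(f1), 1.35)
})

test_that("blob-median fitting tolerates unbalanced localization counts", {
  set.seed(72)
  tpl <- makeTemplate("ring", nFold = 8, diameter = 160)
  acq <- acquisitionModel(dol = 1, locsPerSite = 12, sigmaMeanNm = 2.5)
  es <- replicate(5, ellipticity(fitEllipseToRing(sampleParticle(tpl, acq),
                                                  nSites = 8)))
  expect_true(all(es >= 1 & es < 1.15))  # circular within noise
})

test_that("order parameter hits its defining values", {
  expect_equal(as.numeric(orderParameter(rep(0.7, 5))), 1)
  expect_equal(as.numeric(orderParameter(c(0, pi / 2))), 0,
               tolerance = 1e-12)
  # equispaced angles over [0, pi): exactly balanced
  expect_equal(as.numeric(orderParameter(pi * (0:99) / 100)), 0,
               tolerance = 1e-12)
  # uniform random angles: near 0 in expectation
  set.seed(73)
  expect_lt(abs(as.numeric(orderParameter(runif(4000, 0, pi)))), 0.05)
  expect_error(orderParameter(numeric(0)), "no angles")
})

test_that("order parameter is invariant under a global rotation", {
  set.seed(74)
  th <- runif(20, 0, pi)
  v0 <- as.numeric(orderParameter(th))
  for (shift in c(0.3, 1.2, 2.9))
    expect_equal(as.numeric(orderParameter(th + shift)), v0,
                 tolerance = 1e-12)
})

test_that("classification orders deformed ring classes by ellipticity", {
  # two NPC-like populations with different generating ellipticities
  tpl <- makeTemplate("ring", nFold = 8, diameter = 160)
  spec <- mixtureSpec(list(
    list(template = tpl, fraction = 0.5, deformation = 1.0),
    list(template = tpl, fraction = 0.5, deformation = 1.45)),
    40, seed = 75)
  ps <- makeDataset(spec, acquisitionModel(dol = 0.9, locsPerSite = 10,
                                           sigmaMeanNm = 2))
  dm <- allToAll(ps, registrationConfig(scale = 0.1))
  emb <- mdsEmbed(dm, d = 10)
  cl <- kmeansCluster(emb, 2, nRestarts = 200, seed = 1)
  meanE <- vapply(1:2, function(k) {
    mean(vapply(which(clusterLabels(cl) == k), function(i)
      ellipticity(fitEllipseToRing(particles(ps)[[i]], nSites = 8)),
      numeric(1)))
  }, numeric(1))
  genE <- vapply(1:2, function(k)
    mean(trueClasses(ps)[clusterLabels(cl) == k] == 2L), numeric(1))
  # the class richer in deformed particles has the larger mean fitted e
  expect_equal(order(meanE), order(genE))
})
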