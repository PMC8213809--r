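test_that("templates have the designed geometry", {
  g <- makeTemplate("grid", rows = 3, cols = 4, spacing = 20)
  expect_equal(nrow(coords(g)), 12L)
  dd <- as.matrix(dist(coords(g)))
  diag(dd) <- Inf
  expect_equal(unname(apply(dd, 1, min)), rep(20, 12))  # nearest neighbor
  expect_equal(colMeans(coords(g)), c(x = 0, y = 0))

  r8 <- makeTemplate("ring", nFold = 8, diameter = 160)
  ang <- atan2(coords(r8)[, 2], coords(r8)[, 1])
  gaps <- sort((diff(c(ang, ang[1] + 2 * pi)) * 180 / pi) %% 360)
  expect_equal(gaps, rep(45, 8))
  expect_equal(unname(sqrt(rowSums(coords(r8)^2))), rep(80, 8))

  r9 <- makeTemplate("ring", nFold = 9, diameter = 160)
  ang9 <- atan2(coords(r9)[, 2], coords(r9)[, 1])
  gaps9 <- (diff(c(ang9, ang9[1] + 2 * pi)) * 180 / pi) %% 360
  expect_equal(unname(gaps9), rep(40, 9))

  tet <- makeTemplate("tetrahedron", edge = 100, height = 90)
  expect_equal(ncol(coords(tet)), 3L)
  base <- coords(tet)[1:3, ]
  expect_equal(unname(as.vector(dist(base))), rep(100, 3))
  expect_equal(unname(coords(tet)[4, 3] - base[1, 3]), 90)

  expect_error(makeTemplate("blob"))
  expect_error(makeTemplate("grid", spacing = -5), "spacing")
  expect_error(makeTemplate("ring", diameter = 0), "diameter")
})

test_that("noise-free limit reproduces the template sites exactly", {
  tpl <- makeTemplate("grid")
  acq <- acquisitionModel(dol = 1, locsPerSite = 1, locsDist = "fixed",
                          sigmaMeanNm = 1e-12)
  set.seed(11)
  p <- sampleParticle(tpl, acq)
  expect_equal(nLocs(p), nrow(coords(tpl)))
  # each localization coincides with its site (sigma -> 0)
  expect_lt(max(abs(coords(p) - coords(tpl))), 1e-9)
})

test_that("underlabeling follows the binomial expectation", {
  tpl <- makeTemplate("grid")  # 12 sites
  acq <- acquisitionModel(dol = 0.5, locsPerSite = 1, locsDist = "fixed",
                          sigmaMeanNm = 1)
  set.seed(5)
  nkept <- replicate(3000, nLocs(sampleParticle(tpl, acq)))
  # E = 12 * 0.5 = 6, sd of the mean = sqrt(12*.25/3000) ~ 0.032
  expect_lt(abs(mean(nkept) - 6), 0.15)
})

test_that("mirroring is an exact reflection under a shared seed", {
  tpl <- makeTemplate("dots", letter = "L")
  acq <- fixtureAcq()
  set.seed(21)
  p1 <- sampleParticle(tpl, acq, mirror = FALSE)
  set.seed(21)
  p2 <- sampleParticle(tpl, acq, mirror = TRUE)
  refl <- coords(p1)
  refl[, 2] <- -refl[, 2]
  expect_equal(coords(p2), refl)
  expect_equal(sigmas(p1), sigmas(p2))
})

test_that("datasets are reproducible and labels are bookkept", {
  tpl1 <- makeTemplate("ring", nFold = 8)
  tpl2 <- makeTemplate("ring", nFold = 9)
  spec <- mixtureSpec(list(list(template = tpl1, fraction = 0.98),
                           list(template = tpl2, fraction = 0.02)),
                      500, seed = 99)
  ps1 <- makeDataset(spec, fixtureAcq())
  ps2 <- makeDataset(spec, fixtureAcq())
  expect_identical(lapply(particles(ps1), coords),
                   lapply(particles(ps2), coords))
  expect_identical(trueClasses(ps1), trueClasses(ps2))
  expect_length(trueClasses(ps1), 500)
  # rare-class count: expectation 10 at 2% of 500; generously within 4 sd
  nrare <- sum(trueClasses(ps1) == 2L)
  expect_lt(abs(nrare - 10), 4 * sqrt(500 * 0.02 * 0.98) + 1)

  one <- makeDataset(mixtureSpec(list(list(template = tpl1, fraction = 1)),
                                 20, seed = 1), fixtureAcq())
  expect_true(all(trueClasses(one) == 1L))
})

test_that("localization noise is calibrated to the stored uncertainties", {
  tpl <- makeTemplate("grid", spacing = 60)  # sites far apart vs sigma
  acq <- acquisitionModel(dol = 1, locsPerSite = 1000, locsDist = "fixed",
                          sigmaMeanNm = 2, sigmaShape = 4)
  set.seed(31)
  p <- sampleParticle(tpl, acq)
  # nearest site is the generating site (spacing 60 >> sigma)
  dmat <- as.matrix(dist(rbind(coords(p), coords(tpl))))
  n <- nLocs(p)
  dev <- apply(dmat[seq_len(n), (n + 1):(n + 12), drop = FALSE], 1, min)
  # per-localization: |dev|^2 / sigma^2 ~ chi2_2, so E[dev^2 / sigma^2] = 2
  expect_lt(abs(mean(dev^2 / sigmas(p)^2) - 2), 0.1)
  # population RMS matches the sigma distribution: E[dev^2] = 2 E[sigma^2]
  expect_lt(abs(sqrt(mean(dev^2)) / sqrt(2 * mean(sigmas(p)^2)) - 1), 0.05)
})

test_that("elliptical deformation preserves area and sets the axis ratio", {
  tpl <- makeTemplate("ring", nFold = 64, diameter = 100)
  acq <- acquisitionModel(dol = 1, locsPerSite = 1, locsDist = "fixed",
                          sigmaMeanNm = 1e-12)
  set.seed(41)
  p <- sampleParticle(tpl, acq, deformation = 1.3)
  xr <- diff(range(coords(p)[, 1]))
  yr <- diff(range(coords(p)[, 2]))
  expect_equal(xr / yr, 1.3, tolerance = 1e-6)
  expect_equal(xr * yr, 100^2, tolerance = 1e-6)
})

test_that("invalid mixture specifications are rejected", {
  tpl <- makeTemplate("ring")
  expect_error(mixtureSpec(list(list(template = tpl, fraction = 0.7)),
                           10, seed = 1), "sum to 1")
  expect_error(mixtureSpec(list(list(template = tpl, fraction = 1,
                                     deformation = -2)), 10, seed = 1))
  expect_error(acquisitionModel(dol = 0), "dol")
  expect_error(acquisitionModel(locsPerSite = 0))
})
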