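test_that("rendered images are normalized histograms", {
  set.seed(61)
  p <- sampleParticle(makeTemplate("ring"), fixtureAcq())
  img <- renderImage(p, nPix = 64)
  expect_equal(mean(img), 0, tolerance = 1e-12)
  expect_equal(sum(img^2), 1, tolerance = 1e-12)
  expect_equal(attr(img, "counts"), nLocs(p))
  # a single localization occupies exactly one bin
  one <- LocalizationSet(cbind(0, 0), sigma = 1)
  img1 <- renderImage(one, nPix = 16, extent = c(-10, 10, -10, 10))
  expect_equal(sum(img1 > mean(img1)), 1L)
  expect_equal(attr(img1, "counts"), 1L)
  # localizations outside the extent are not binned
  img2 <- renderImage(p, nPix = 16, extent = c(-1, 1, -1, 1))
  expect_lte(attr(img2, "counts"), nLocs(p))
  # optional pre-blur keeps the normalization contract
  imgB <- renderImage(p, nPix = 64, blurPx = 1.5)
  expect_equal(mean(imgB), 0, tolerance = 1e-12)
  expect_equal(sum(imgB^2), 1, tolerance = 1e-12)
  expect_gt(sum(imgB * renderImage(p, nPix = 64)), 0.2)  # same structure
})

test_that("identical images give a rank-1 eigen decomposition", {
  set.seed(62)
  p <- sampleParticle(makeTemplate("dots", letter = "T"), fixtureAcq())
  img <- renderImage(p, nPix = 32)
  eis <- eigenImages(list(img, img, img))
  expect_equal(eis@eigenImages[, , 1], unclass(img), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(eis@singularValues[2] / eis@singularValues[1], 1e-10)
  expect_lt(eis@singularValues[3] / eis@singularValues[1], 1e-10)
})

test_that("the K x K Gram trick matches the direct decomposition", {
  set.seed(63)
  imgs <- lapply(1:4, function(k) {
    m <- matrix(rnorm(64), 8, 8)
    m <- m - mean(m)
    m / sqrt(sum(m^2))
  })
  eis <- eigenImages(imgs)
  X <- vapply(imgs, as.numeric, numeric(64))
  direct <- eigen(X %*% t(X), symmetric = TRUE)  # full covariance, 64 x 64
  expect_equal(eis@singularValues, direct$values[1:4], tolerance = 1e-9)
  for (k in 1:4) {
    u <- direct$vectors[, k]
    v <- as.numeric(eis@eigenImages[, , k])
    expect_equal(abs(sum(u * v)), 1, tolerance = 1e-9)  # same up to sign
  }
  # spectral identity: sum of singular values equals trace of X^T X
  expect_equal(sum(eis@singularValues), sum(diag(crossprod(X))),
               tolerance = 1e-9)
})

test_that("eigen image signs are fixed reproducibly", {
  set.seed(64)
  imgs <- lapply(1:3, function(k) {
    m <- matrix(rnorm(36), 6, 6)
    m <- m - mean(m)
    m / sqrt(sum(m^2))
  })
  e1 <- eigenImages(imgs)
  e2 <- eigenImages(rev(imgs))
  # first eigen image identical regardless of stacking order (up to fp noise)
  expect_equal(abs(sum(e1@eigenImages[, , 1] * e2@eigenImages[, , 1])), 1,
               tolerance = 1e-9)
  expect_gte(sum(e1@eigenImages[, , 1] * rowMeans(vapply(imgs, as.numeric,
                                                         numeric(36)))), 0)
})

test_that("projection weights separate distinct structures", {
  acq <- fixtureAcq()
  set.seed(65)
  mkimg <- function(tpl) {
    p <- sampleParticle(tpl, acq)
    renderImage(p, nPix = 48, extent = c(-80, 80, -80, 80))
  }
  imgs <- c(lapply(1:3, function(i) mkimg(makeTemplate("dots", letter = "T"))),
            lapply(1:3, function(i) mkimg(makeTemplate("ring", diameter = 100))))
  eis <- eigenImages(imgs)
  pm <- projectAndMerge(eis, 2)
  expect_equal(pm$mergeMap[1:3], rep(pm$mergeMap[1], 3))
  expect_equal(pm$mergeMap[4:6], rep(pm$mergeMap[4], 3))
  expect_true(pm$mergeMap[1] != pm$mergeMap[4])
  # C = 1 merges everything
  expect_equal(projectAndMerge(eis, 1)$mergeMap, rep(1L, 6))
  expect_error(projectAndMerge(eis, 7), "C must be")
})

test_that("alignment is rigid and recovers a pre-rotated copy", {
  set.seed(66)
  base <- sampleParticle(makeTemplate("dots", letter = "L"),
                         acquisitionModel(dol = 1, locsPerSite = 10,
                                          sigmaMeanNm = 1.5))
  rot <- rigidTransform(theta = 2.1, t = c(25, 5))
  copy <- LocalizationSet(applyTransform(rot, coords(base)), sigmas(base),
                          id = "copy")
  al <- alignClusters(list(base, copy), registrationConfig(scale = 0.05))
  d1 <- dist(coords(al$aligned[[1]]))
  d2 <- dist(coords(al$aligned[[2]]))
  expect_equal(as.vector(dist(coords(base))), as.vector(d1),
               tolerance = 1e-9)  # internal geometry untouched
  # after alignment the pair overlaps like the self-match
  sAligned <- bhattacharyyaScore(al$aligned[[1]], al$aligned[[2]])
  sSelf <- bhattacharyyaScore(base, base)
  expect_gt(sAligned / sSelf, 0.95)
  # single cluster returned unchanged
  al1 <- alignClusters(list(base))
  expect_equal(coords(al1$aligned[[1]]), coords(base))
})

test_that("a mirrored subpopulation is isolated end to end", {
  # chiral F-shaped dot pattern; 15% of the particles are imaged mirrored.
  # High K then eigen-image merging to two classes must put >= 80% of the
  # true mirrored particles into the minority class. Fusion refinement and
  # rendering pre-blur are the recommended settings for sparse asymmetric
  # patterns (see the vignette).
  tplF <- makeTemplate("dots", dotCoords = rbind(
    cbind(-1, -2:2), cbind(c(0, 1, 2), 2), cbind(c(0, 1), 0)), name = "F10")
  spec <- mixtureSpec(list(list(template = tplF, fraction = 0.85),
                           list(template = tplF, fraction = 0.15,
                                mirror = TRUE)),
                      60, seed = 91)
  ps <- makeDataset(spec, acquisitionModel(dol = 0.8, locsPerSite = 10,
                                           sigmaMeanNm = 2))
  cfgL <- registrationConfig(scale = 0.03, maxLocsOptim = 32L,
                             maxEvalCoarse = 100L)
  dm <- allToAll(ps, cfgL)
  emb <- mdsEmbed(dm, d = 30, seed = 91)
  cl <- kmeansCluster(emb, 6, nRestarts = 500, seed = 91,
                      silhouetteDims = 0L)
  em <- eigenMerge(ps, dm, cl, C = 2, cfg = cfgL, blurPx = 4,
                   refineFusion = TRUE)
  mir <- trueClasses(ps) == 2L
  minority <- which.min(table(factor(em$classLabels, levels = 1:2)))
  expect_gte(mean(em$classLabels[mir] == minority), 0.8)
})

test_that("merging conserves particles and localizations", {
  ps <- fixtureRingSet(12, seed = 67)
  dm <- allToAll(ps, registrationConfig(scale = 0.1))
  emb <- mdsEmbed(dm, d = 5)
  cl <- kmeansCluster(emb, 4, nRestarts = 100, seed = 1)
  em <- eigenMerge(ps, dm, cl, C = 2, nPix = 64)
  expect_length(em$classLabels, 12L)
  expect_equal(sort(unique(em$mergeMap)), 1:2)
  totalLocs <- sum(vapply(particles(ps), nLocs, integer(1)))
  expect_equal(sum(vapply(em$classes, nLocs, integer(1))), totalLocs)
  expect_equal(sum(vapply(em$fusions, function(f) nLocs(f@locs),
                          integer(1))), totalLocs)
})
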