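test_that("stress has its closed-form values and matches the oracle", {
  X <- cbind(c(0, 3, 0), c(0, 0, 4))
  D <- as.matrix(dist(X))
  expect_equal(mdsStress(D, X), 0)
  # all dissimilarities 1, all points coincident: numerator = denominator
  D1 <- matrix(1, 4, 4) - diag(4)
  X0 <- matrix(0, 4, 2)
  expect_equal(mdsStress(D1, X0), 1)
  set.seed(2)
  D4 <- as.matrix(dist(matrix(rnorm(8), 4)))
  X4 <- matrix(rnorm(12), 4)
  expect_equal(mdsStress(D4, X4), oracleStress(D4, X4), tolerance = 1e-12)
  expect_error(mdsStress(matrix(0, 3, 3), X), "zero")
})

test_that("MDS reproduces a Euclidean configuration", {
  set.seed(4)
  Y <- matrix(rnorm(30), 10, 3)
  D <- as.matrix(dist(Y))
  emb <- mdsEmbed(D, d = 3)
  expect_lt(stressValue(emb), 1e-6)
  expect_lt(procrustesResidual(Y, coords(emb)), 1e-4)
  # distance preservation improves to near-exactness
  expect_lt(max(abs(as.matrix(dist(coords(emb))) - D)), 1e-4)
})

test_that("MDS stress trace is non-increasing and d is capped", {
  set.seed(5)
  D <- as.matrix(dist(matrix(rnorm(24), 12)))
  emb <- mdsEmbed(D, d = 6)
  expect_true(all(diff(emb@trace) <= 1e-12))
  expect_warning(embBig <- mdsEmbed(D, d = 20), "capped")
  expect_equal(ncol(coords(embBig)), 11L)
})

test_that("a pair embeds exactly in one dimension", {
  D <- matrix(c(0, 7, 7, 0), 2)
  emb <- mdsEmbed(D, d = 1)
  expect_equal(abs(diff(coords(emb)[, 1])), 7, tolerance = 1e-9)
})

test_that("k-means separates well-separated blobs and respects the objective", {
  set.seed(6)
  X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 10), 20))
  truth <- rep(1:2, each = 20)
  cl <- kmeansCluster(X, 2, nRestarts = 25, seed = 1)
  expect_equal(matchAccuracy(clusterLabels(cl), truth), 1)
  # returned objective is no worse than independent single restarts
  for (s in 1:5) {
    set.seed(s)
    km <- suppressWarnings(kmeans(X, centers = X[sample(40, 2), ],
                                  algorithm = "Lloyd", iter.max = 100))
    expect_lte(cl@totWithinSS, km$tot.withinss + 1e-9)
  }
  # K = N: every point its own cluster, objective 0
  clN <- kmeansCluster(X[1:6, ], 6, nRestarts = 5, seed = 1)
  expect_equal(clN@totWithinSS, 0)
  expect_equal(sort(clusterLabels(clN)), 1:6)
  expect_error(kmeansCluster(X, 50, seed = 1), "K must be")
})

test_that("k-means with many restarts attains the exhaustive optimum", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(16), 8, 2)
    best <- oracleBestPartition(X, 2)
    cl <- kmeansCluster(X, 2, nRestarts = 100, seed = seed)
    expect_equal(cl@totWithinSS, best, tolerance = 1e-9)
  }
})

test_that("k-means labels are deterministic given a seed", {
  set.seed(8)
  X <- matrix(rnorm(60), 20, 3)
  c1 <- kmeansCluster(X, 3, nRestarts = 50, seed = 11)
  c2 <- kmeansCluster(X, 3, nRestarts = 50, seed = 11)
  expect_identical(clusterLabels(c1), clusterLabels(c2))
})

test_that("silhouette matches the hand-computed 4-point case and conventions", {
  # points on a line: 0, 1, 10, 11; clusters {1,2}, {3,4}
  X <- cbind(c(0, 1, 10, 11), 0)
  sv <- silhouetteValues(X, c(1, 1, 2, 2))
  # point 1: a = 1, b = (10+11)/2 = 10.5 -> (10.5-1)/10.5
  expect_equal(sv$values,
               c((10.5 - 1) / 10.5, (9.5 - 1) / 9.5,
                 (9.5 - 1) / 9.5, (10.5 - 1) / 10.5))
  expect_equal(sv$mean, mean(sv$values))
  expect_true(all(sv$values >= -1 & sv$values <= 1))
  # singleton cluster gets 0
  sv2 <- silhouetteValues(X, c(1, 1, 1, 2))
  expect_equal(sv2$values[4], 0)
  expect_error(silhouetteValues(X, rep(1, 4)), "2 clusters")
})

test_that("silhouette agrees with the reference implementation", {
  skip_if_not_installed("cluster")
  for (seed in 1:4) {
    set.seed(seed)
    X <- matrix(rnorm(20), 10, 2)
    lab <- sample(1:3, 10, replace = TRUE)
    if (length(unique(lab)) < 2) next
    ours <- silhouetteValues(X, lab)$values
    ref <- cluster::silhouette(lab, dist(X))
    # reference assigns 0 to singletons too
    expect_equal(ours, unname(ref[, "sil_width"]), tolerance = 1e-12)
  }
})

test_that("mean silhouette grows toward 1 with cluster separation", {
  set.seed(9)
  base <- rbind(matrix(rnorm(30), 15, 2), matrix(rnorm(30), 15, 2))
  seps <- c(5, 20, 100)
  ms <- vapply(seps, function(s) {
    X <- base + rbind(matrix(0, 15, 2), matrix(s, 15, 2))
    silhouetteValues(X, rep(1:2, each = 15))$mean
  }, numeric(1))
  expect_true(all(diff(ms) > 0))
  expect_gt(ms[3], 0.97)
})

test_that("suggestK finds the generating cluster count on separable data", {
  set.seed(10)
  ctrs <- matrix(c(0, 0, 40, 0, 0, 40, 40, 40), 4, 2, byrow = TRUE)
  Y <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(24, 0, 2), 12, 2), 2, -ctrs[k, ])))
  D <- as.matrix(dist(Y))
  sg <- suggestK(D, kRange = 2:7, d = 5, nRestarts = 50, seed = 1)
  expect_equal(sg$suggested, 4L)
  # 2-cluster case
  Y2 <- Y[1:24, ]
  sg2 <- suggestK(as.matrix(dist(Y2)), kRange = 2:5, d = 4, nRestarts = 50,
                  seed = 1)
  expect_equal(sg2$suggested, 2L)
  # single-class data: flat profile, no failure
  set.seed(11)
  Y1 <- matrix(rnorm(60), 30, 2)
  sg1 <- suggestK(as.matrix(dist(Y1)), kRange = 2:5, d = 4, nRestarts = 30,
                  seed = 1)
  expect_s3_class(sg1$table, "data.frame")
  expect_true(all(is.finite(sg1$table$meanSilhouette)))
  expect_lt(max(sg1$table$meanSilhouette), 0.6)  # no strong structure
})
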