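# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (plain R double loops, exhaustive enumeration) so they
# are independent of the implementation paths they check.

# Bhattacharyya similarity by direct double summation (2D isotropic or 3D
# with optional anisotropic axial uncertainties)
oracleBhat <- function(a, b, tr = NULL) {
  ca <- coords(a); cb <- coords(b)
  if (is.null(tr)) tr <- identityTransform(ncol(ca))
  cb <- t(tr$R %*% t(cb) + tr$t)
  sa <- sigmas(a); sb <- sigmas(b)
  saz <- sigmasAxial(a); sbz <- sigmasAxial(b)
  aniso <- ncol(ca) == 3 && length(saz) > 0 && length(sbz) > 0
  acc <- 0
  for (i in seq_len(nrow(ca))) {
    for (j in seq_len(nrow(cb))) {
      dvec <- ca[i, ] - cb[j, ]
      if (ncol(ca) == 2) {
        s2 <- sa[i]^2 + sb[j]^2
        acc <- acc + exp(-0.5 * sum(dvec^2) / s2) / s2
      } else {
        sxy <- sa[i]^2 + sb[j]^2
        sz <- if (aniso) saz[i]^2 + sbz[j]^2 else sxy
        q <- 0.5 * ((dvec[1]^2 + dvec[2]^2) / sxy + dvec[3]^2 / sz)
        acc <- acc + exp(-q) / (sxy * sxy * sz)^(1 / 3)
      }
    }
  }
  acc / (nrow(ca) * nrow(cb))
}

# exact overlap integral of two uniform-width GMMs: pairwise Gaussian product
# integral N(d; 0, 2 s^2 I) summed with weights 1/(Ka*Kb)
oracleGmm <- function(a, b, scaleNm, tr = NULL) {
  ca <- coords(a); cb <- coords(b)
  d <- ncol(ca)
  if (is.null(tr)) tr <- identityTransform(d)
  cb <- t(tr$R %*% t(cb) + tr$t)
  acc <- 0
  for (i in seq_len(nrow(ca))) {
    for (j in seq_len(nrow(cb))) {
      r2 <- sum((ca[i, ] - cb[j, ])^2)
      acc <- acc + exp(-r2 / (4 * scaleNm^2)) /
        (4 * pi * scaleNm^2)^(d / 2)
    }
  }
  acc / (nrow(ca) * nrow(cb))
}

# normalized metric stress by direct pair summation
oracleStress <- function(D, X) {
  N <- nrow(D)
  num <- 0; den <- 0
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      dij <- sqrt(sum((X[i, ] - X[j, ])^2))
      num <- num + (D[i, j] - dij)^2
      den <- den + D[i, j]^2
    }
  }
  sqrt(num / den)
}

# minimal k-means objective (total within-cluster sum of squared distances to
# the centroid) over ALL assignments of N points to K non-empty groups
oracleBestPartition <- function(X, K) {
  N <- nrow(X)
  stopifnot(N <= 9)
  grid <- do.call(expand.grid, rep(list(seq_len(K)), N))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    g <- as.integer(grid[r, ])
    if (length(unique(g)) != K) next
    obj <- 0
    for (k in seq_len(K)) {
      pts <- X[g == k, , drop = FALSE]
      ctr <- colMeans(pts)
      obj <- obj + sum(sweep(pts, 2, ctr)^2)
    }
    if (obj < best) best <- obj
  }
  best
}

# residual after optimal rigid alignment (rotation/reflection + translation)
procrustesResidual <- function(X, Y) {
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  sv <- svd(crossprod(Y, X))
  R <- sv$u %*% t(sv$v)
  sqrt(mean(rowSums((Y %*% R - X)^2)))
}

# best label agreement over all permutations of predicted labels (K <= 6)
matchAccuracy <- function(pred, truth) {
  ks <- sort(unique(truth))
  ps <- sort(unique(pred))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  if (length(ps) > length(ks)) return(NA_real_)
  best <- 0
  for (p in perms(ks)) {
    mapped <- p[match(pred, ps)]
    best <- max(best, mean(mapped == truth))
  }
  best
}

# small standard fixtures ------------------------------------------------------

fixtureAcq <- function(...) {
  args <- utils::modifyList(list(dol = 0.7, locsPerSite = 6, sigmaMeanNm = 3),
                            list(...))
  do.call(acquisitionModel, args)
}

# a small single-class ring dataset
fixtureRingSet <- function(n = 10, nFold = 8, seed = 42, ...) {
  tpl <- makeTemplate("ring", nFold = nFold, diameter = 160)
  makeDataset(mixtureSpec(list(list(template = tpl, fraction = 1)), n,
                          seed = seed), fixtureAcq(...))
}

# random small localization set for oracle checks
fixtureRandomLocs <- function(n, d = 2, seed = 1, spread = 40) {
  withr::with_seed(seed, {
    coords <- matrix(runif(n * d, -spread, spread), n, d)
    sigma <- runif(n, 1, 4)
    sz <- if (d == 3) runif(n, 4, 10) else numeric(0)
    LocalizationSet(coords, sigma, sz, id = paste0("r", seed))
  })
}

randomTransform <- function(d = 2, seed = 1) {
  withr::with_seed(seed, {
    if (d == 2) rigidTransform(theta = runif(1, 0, 2 * pi),
                               t = runif(2, -20, 20))
    else {
      q <- rnorm(4); q <- q / sqrt(sum(q^2))
      R <- matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] + q[1] * q[4]),
                    2 * (q[2] * q[4] - q[1] * q[3]),
                    2 * (q[2] * q[3] - q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
                    2 * (q[3] * q[4] + q[1] * q[2]),
                    2 * (q[2] * q[4] + q[1] * q[3]),
                    2 * (q[3] * q[4] - q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
                  3, 3)
      rigidTransform(R = R, t = runif(3, -20, 20))
    }
  })
}
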