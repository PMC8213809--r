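# Continuous shape variation of ring-like classes: ellipse fitting to
# binding-site medians and an orientation order parameter.

#' Fit an ellipse to a ring-like localization cloud
#'
#' Localizations are grouped into `nSites` blobs by k-means. The seeding is
#' angular and data-adaptive: sorting the localizations by polar angle around
#' the centroid and cutting at the `nSites` largest angular gaps yields one
#' contiguous arc per blob (rotation-invariant, and it avoids splitting a
#' blob under random seeding); the arc means seed Lloyd's iterations. The
#' coordinate-wise median of each blob is computed, and a direct
#' least-squares conic fit constrained to ellipses is applied to the medians.
#' Fitting medians rather than raw localizations makes the result insensitive
#' to unbalanced localization counts per site.
#'
#' @param locs a [LocalizationSet-class] (2D; 3D input uses x, y).
#' @param nSites number of binding-site blobs on the ring.
#' @param seed unused (kept for interface stability; seeding is
#'   deterministic).
#' @return An [EllipseFit-class] with ellipticity `e = a/b >= 1`.
#' @examples
#' ang <- 2 * pi * (0:7) / 8
#' ring <- LocalizationSet(80 * cbind(cos(ang), sin(ang)), sigma = 1)
#' ellipticity(fitEllipseToRing(ring))  # 1 (circle)
#' @export
fitEllipseToRing <- function(locs, nSites = 8L, seed = NULL) {
  stopifnot(is(locs, "LocalizationSet"))
  xy <- locs@coords[, 1:2, drop = FALSE]
  n <- nrow(xy)
  if (n < nSites) stop("fewer localizations than sites")
  ctr <- colMeans(xy)
  ang <- atan2(xy[, 2] - ctr[2], xy[, 1] - ctr[1])
  ord <- order(ang)
  gaps <- diff(c(ang[ord], ang[ord[1]] + 2 * pi))
  cuts <- sort(order(gaps, decreasing = TRUE)[seq_len(nSites)])
  lab0 <- integer(n)
  g <- 1L
  for (k in seq_along(ord)) {
    lab0[ord[k]] <- g
    if (k %in% cuts) g <- g + 1L
  }
  lab0[lab0 > nSites] <- 1L  # points past the last cut wrap around
  seeds <- t(vapply(seq_len(nSites), function(s) {
    m <- xy[lab0 == s, , drop = FALSE]
    if (nrow(m)) colMeans(m) else ctr
  }, numeric(2)))
  km <- tryCatch(
    suppressWarnings(kmeans(xy, centers = seeds, iter.max = 100L,
                            algorithm = "Lloyd")),
    error = function(e) list(cluster = lab0))
  meds <- t(vapply(seq_len(nSites), function(s) {
    m <- xy[km$cluster == s, , drop = FALSE]
    if (!nrow(m)) c(NA_real_, NA_real_) else apply(m, 2, median)
  }, numeric(2)))
  meds <- unique(meds[stats::complete.cases(meds), , drop = FALSE])
  fitEllipseDirect(meds)
}

#' Direct least-squares ellipse fit
#'
#' Fits the conic `ax^2 + bxy + cy^2 + dx + ey + f = 0` to points under the
#' ellipse constraint `4ac - b^2 = 1` (Fitzgibbon's direct method), and
#' converts the conic to center, semi-axes and orientation.
#'
#' @param points numeric matrix (n x 2), n >= 5 non-degenerate points.
#' @return An [EllipseFit-class].
#' @export
fitEllipseDirect <- function(points) {
  P <- as.matrix(points)
  if (nrow(P) < 5L) stop("ellipse fit needs at least 5 points")
  # center/scale for conditioning
  mu <- colMeans(P)
  sc <- mean(apply(P, 2, function(v) stats::sd(v)))
  if (!is.finite(sc) || sc <= 0) stop("degenerate points (zero spread)")
  x <- (P[, 1] - mu[1]) / sc
  y <- (P[, 2] - mu[2]) / sc
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate point configuration (collinear medians?)"))
  M <- S1 + S2 %*% Tm
  C1inv <- matrix(c(0, 0, 0.5, 0, -1, 0, 0.5, 0, 0), 3, 3)
  eg <- eigen(C1inv %*% M)
  vals <- Re(eg$values)
  vecs <- Re(eg$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 0)  # exactly one eigenvector satisfies the constraint
  if (!length(ok)) stop("no ellipse solution (degenerate input)")
  if (length(ok) > 1L) ok <- ok[which.max(vals[ok])]
  a1 <- vecs[, ok]
  par <- c(a1, Tm %*% a1)  # (A, B, C, D, E, F) in scaled frame
  A <- par[1]; B <- par[2]; Cc <- par[3]; Dd <- par[4]; E <- par[5]; Ff <- par[6]
  den <- 4 * A * Cc - B^2
  cx <- (B * E - 2 * Cc * Dd) / den
  cy <- (B * Dd - 2 * A * E) / den
  # value of the quadratic form at the center
  Fc <- Ff + A * cx^2 + B * cx * cy + Cc * cy^2 + Dd * cx + E * cy
  Mq <- matrix(c(A, B / 2, B / 2, Cc), 2, 2) / (-Fc)
  ee <- eigen(Mq, symmetric = TRUE)
  if (any(ee$values <= 0)) stop("no ellipse solution (degenerate input)")
  axes <- 1 / sqrt(ee$values)          # descending eigenvalue -> minor first
  aLen <- max(axes) * sc
  bLen <- min(axes) * sc
  majVec <- ee$vectors[, which.min(ee$values)]
  theta <- atan2(majVec[2], majVec[1]) %% pi
  new("EllipseFit", center = c(cx * sc + mu[1], cy * sc + mu[2]),
      a = aLen, b = bLen, theta = theta, e = aLen / bLen)
}

#' Orientation order parameter
#'
#' `mean(cos(2 * (theta - director)))` over a set of ellipse orientations,
#' where the director is the circular mean angle computed with period pi
#' (`0.5 * atan2(mean(sin 2 theta), mean(cos 2 theta))`). Returns 1 for
#' complete alignment and 0 in expectation for uniformly random
#' orientations.
#'
#' @param angles ellipse orientations in radians.
#' @return The order parameter (scalar), with the director in attribute
#'   `director`.
#' @examples
#' orderParameter(c(0.3, 0.3, 0.3))          # 1
#' orderParameter(c(0, pi / 2))              # 0
#' @export
orderParameter <- function(angles) {
  if (!length(angles)) stop("no angles supplied")
  director <- 0.5 * atan2(mean(sin(2 * angles)), mean(cos(2 * angles)))
  out <- mean(cos(2 * (angles - director)))
  attr(out, "director") <- director
  out
}
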