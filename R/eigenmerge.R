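# Merging K reconstructed clusters into C < K final classes via eigen images.
#
# The K cluster reconstructions are mutually aligned (registration only; no
# pooling), rendered into a shared pixel frame, normalized, and decomposed by
# SVD of the small K x K Gram matrix (the eigen images are recovered as
# u = X a). All K images are projected onto the first eigen image and the
# 1D weights are grouped by average-linkage hierarchical clustering.

#' Mutually align cluster reconstructions
#'
#' Runs an all-to-all registration on the K cluster reconstructions and
#' applies the optimal transforms so all clusters share the frame of the
#' reconstruction with the highest mean similarity to the others. Only the
#' transforms are applied; no localizations are merged.
#'
#' @param fusions list of [FusedReconstruction-class] (or
#'   [LocalizationSet-class]) objects.
#' @param cfg [RegistrationConfig-class] for the mutual registration.
#' @param maxLocs reconstructions are deterministically subsampled to this
#'   many localizations for the registration itself (a reconstruction pools
#'   all member particles, so a moderate subsample already fixes the pose
#'   precisely); the transforms are applied to the full clouds.
#' @return A list: `aligned` (list of [LocalizationSet-class]),
#'   `transforms`, `reference` (index), `dm` (the
#'   [DissimilarityMatrix-class] of the subsampled cluster reconstructions).
#' @export
alignClusters <- function(fusions, cfg = NULL, maxLocs = 150L) {
  locs <- lapply(fusions, function(f)
    if (is(f, "FusedReconstruction")) f@locs else f)
  stopifnot(all(vapply(locs, is, logical(1), "LocalizationSet")))
  K <- length(locs)
  if (K == 1L)
    return(list(aligned = locs,
                transforms = list(identityTransform(ncol(locs[[1]]@coords))),
                reference = 1L, dm = NULL))
  if (is.null(cfg)) cfg <- registrationConfig(scale = 0.1)
  for (k in seq_len(K)) locs[[k]]@id <- sprintf("cluster%02d", k)
  sub <- lapply(locs, function(p) {
    n <- nLocs(p)
    if (n <= maxLocs) return(p)
    idx <- floor((seq_len(maxLocs) - 0.5) * n / maxLocs) + 1L
    LocalizationSet(p@coords[idx, , drop = FALSE], p@sigma[idx],
                    if (length(p@sigmaZ)) p@sigmaZ[idx] else numeric(0),
                    id = p@id)
  })
  dm <- allToAll(sub, cfg)
  Ssub <- dm@S
  diag(Ssub) <- NA
  ref <- which.max(rowMeans(Ssub, na.rm = TRUE))
  aligned <- vector("list", K)
  transforms <- vector("list", K)
  for (k in seq_len(K)) {
    tr <- if (k == ref) identityTransform(dm@dims) else pairTransform(dm, ref, k)
    transforms[[k]] <- tr
    p <- locs[[k]]
    aligned[[k]] <- LocalizationSet(applyTransform(tr, p@coords), p@sigma,
                                    p@sigmaZ, id = p@id)
  }
  list(aligned = aligned, transforms = transforms, reference = ref, dm = dm)
}

#' Shared rendering extent of aligned clusters
#'
#' Bounding box of all localizations, padded by `pad` on each side.
#'
#' @param locsList list of [LocalizationSet-class].
#' @param pad fractional padding.
#' @return `c(xmin, xmax, ymin, ymax)` in nm.
#' @export
sharedExtent <- function(locsList, pad = 0.1) {
  allc <- do.call(rbind, lapply(locsList, function(p) p@coords[, 1:2]))
  rx <- range(allc[, 1])
  ry <- range(allc[, 2])
  w <- max(diff(rx), diff(ry), 1e-9)
  c(rx[1] - pad * w, rx[2] + pad * w, ry[1] - pad * w, ry[2] + pad * w)
}

#' Render a localization cloud into a normalized pixel image
#'
#' Bins the (x, y) localizations into an `nPix` x `nPix` histogram over
#' `extent`, then normalizes the image to zero mean and unit 2-norm. As a
#' rule of thumb the resulting pixel size should be about 1/4 of the
#' localization uncertainty.
#'
#' @param locs a [LocalizationSet-class].
#' @param nPix image side length in pixels.
#' @param extent `c(xmin, xmax, ymin, ymax)` shared by all clusters being
#'   compared.
#' @param blurPx optional Gaussian pre-blur (standard deviation in pixels,
#'   0 = raw histogram).
#' @return An `nPix` x `nPix` matrix with attribute `pixelNm`; attribute
#'   `counts` gives the number of binned (in-extent) localizations.
#' @export
renderImage <- function(locs, nPix = 400L, extent = NULL, blurPx = 0) {
  stopifnot(is(locs, "LocalizationSet"))
  if (nLocs(locs) < 1L) stop("empty localization set")
  if (is.null(extent)) extent <- sharedExtent(list(locs))
  xy <- locs@coords[, 1:2, drop = FALSE]
  ix <- floor((xy[, 1] - extent[1]) / (extent[2] - extent[1]) * nPix) + 1L
  iy <- floor((xy[, 2] - extent[3]) / (extent[4] - extent[3]) * nPix) + 1L
  ok <- ix >= 1L & ix <= nPix & iy >= 1L & iy <= nPix
  img <- matrix(0, nPix, nPix)
  if (any(ok)) {
    tab <- tabulate((iy[ok] - 1L) * nPix + ix[ok], nbins = nPix * nPix)
    img[] <- tab
  }
  counts <- sum(ok)
  if (blurPx > 0) {
    r <- max(1L, ceiling(3 * blurPx))
    k <- dnorm(-r:r, sd = blurPx)
    k <- k / sum(k)
    blur1 <- function(m) apply(m, 2, function(v)
      convolve(v, rev(k), type = "open")[(r + 1):(r + length(v))])
    img <- t(blur1(t(blur1(img))))
  }
  img <- img - mean(img)
  nrm <- sqrt(sum(img^2))
  if (nrm > 0) img <- img / nrm
  attr(img, "pixelNm") <- (extent[2] - extent[1]) / nPix
  attr(img, "counts") <- counts
  img
}

#' Eigen images of a set of rendered clusters
#'
#' Stacks the K normalized images as columns of X (nPix^2 x K) and computes
#' the singular vectors of the covariance XX^T through the small K x K Gram
#' matrix X^T X: if `X^T X a = s a`, then `u = X a` is a singular vector of
#' XX^T. Eigen images are re-normalized to unit 2-norm and their sign is
#' fixed so the projection onto the mean image is non-negative. Projections
#' of the K images onto the first eigen image are returned as weights.
#'
#' @param images list of equally sized image matrices (zero mean, unit
#'   2-norm; see [renderImage()]), or an nPix x nPix x K array.
#' @param extent optional shared extent (stored for provenance).
#' @return An [EigenImageSet-class] (mergeMap empty until
#'   [projectAndMerge()]).
#' @export
eigenImages <- function(images, extent = c(0, 1, 0, 1)) {
  if (is.array(images) && length(dim(images)) == 3L)
    images <- lapply(seq_len(dim(images)[3]), function(k) images[, , k])
  K <- length(images)
  if (K < 2L) stop("eigen images need at least 2 cluster images")
  nPix <- nrow(images[[1]])
  X <- vapply(images, as.numeric, numeric(nPix * ncol(images[[1]])))
  G <- crossprod(X)                      # K x K Gram matrix X^T X
  eg <- eigen(G, symmetric = TRUE)
  sv <- pmax(eg$values, 0)
  U <- X %*% eg$vectors                  # lift: u = X a
  nrm <- sqrt(colSums(U^2))
  nrm[nrm == 0] <- 1
  U <- sweep(U, 2, nrm, "/")
  meanImg <- rowMeans(X)
  for (k in seq_len(K)) {
    pr <- sum(U[, k] * meanImg)
    if (pr < 0 || (pr == 0 && {
      nz <- which(U[, k] != 0)
      length(nz) && U[nz[1], k] < 0
    })) U[, k] <- -U[, k]
  }
  weights <- as.numeric(crossprod(X, U[, 1]))
  imgArr <- array(X, dim = c(nPix, ncol(images[[1]]), K))
  eigArr <- array(U, dim = c(nPix, ncol(images[[1]]), K))
  new("EigenImageSet", images = imgArr, eigenImages = eigArr,
      singularValues = sv, weights = weights, mergeMap = integer(0),
      extent = extent, nPix = as.integer(nPix))
}

#' Merge clusters by their first-eigen-image weights
#'
#' Groups the K projection weights into C classes by 1D average-linkage
#' hierarchical agglomerative clustering, and (if aligned cluster
#' localizations are supplied) pools the localizations of co-assigned
#' clusters into the final classes. Class ids are ordered by class size
#' (descending), so rare classes come last.
#'
#' @param eis an [EigenImageSet-class].
#' @param C desired number of final classes (1..K).
#' @param aligned optional list of aligned [LocalizationSet-class] (from
#'   [alignClusters()]); the clusters are already in one frame, so merging a
#'   class pools their localizations.
#' @return A list: `mergeMap` (integer K -> C), `eis` (updated), and
#'   `classes` (list of pooled [LocalizationSet-class], or NULL).
#' @export
projectAndMerge <- function(eis, C, aligned = NULL) {
  stopifnot(is(eis, "EigenImageSet"))
  K <- length(eis@weights)
  C <- as.integer(C)
  if (C < 1L || C > K) stop("C must be in 1..K")
  map <- if (C == 1L) rep(1L, K) else {
    hc <- hclust(dist(eis@weights), method = "average")
    as.integer(cutree(hc, k = C))
  }
  # relabel classes by size, large to small (rare class = highest id)
  if (!is.null(aligned)) {
    sz <- vapply(split(vapply(aligned, nLocs, integer(1)), map), sum,
                 numeric(1))
  } else {
    sz <- as.numeric(table(factor(map, levels = seq_len(C))))
  }
  ord <- order(sz, decreasing = TRUE)
  relabel <- integer(C)
  relabel[ord] <- seq_len(C)
  map <- relabel[map]
  eis@mergeMap <- map
  classes <- NULL
  if (!is.null(aligned)) {
    stopifnot(length(aligned) == K)
    classes <- lapply(seq_len(C), function(cc) {
      mem <- which(map == cc)
      coords <- do.call(rbind, lapply(aligned[mem], function(p) p@coords))
      sigma <- unlist(lapply(aligned[mem], function(p) p@sigma))
      sigmaZ <- unlist(lapply(aligned[mem], function(p) p@sigmaZ))
      LocalizationSet(coords, sigma, sigmaZ %||% numeric(0),
                      id = sprintf("class%d", cc))
    })
  }
  list(mergeMap = map, eis = eis, classes = classes)
}

#' Eigen-image merging of clustered particles (convenience wrapper)
#'
#' Fuses each cluster, aligns the K reconstructions, renders them into a
#' shared frame, computes eigen images, and merges the clusters into C final
#' classes. Returns per-particle class labels.
#'
#' @param particles the full particle set.
#' @param dm [DissimilarityMatrix-class] from [allToAll()].
#' @param clusters a [ClusterResult-class] (or integer labels).
#' @param C number of final classes.
#' @param cfg [RegistrationConfig-class] for the cluster alignment (defaults
#'   to the scale of `dm`).
#' @param nPix rendering resolution.
#' @param blurPx optional Gaussian pre-blur of the renderings (pixels);
#'   useful when sparse clusters leave the raw histograms too empty for the
#'   first eigen image to capture structural (e.g. chirality) contrast.
#' @param refineFusion re-register each member against its cluster's pooled
#'   cloud once before rendering; helps asymmetric low-symmetry templates
#'   whose pairwise registrations occasionally miss the right basin.
#' @return A list: `classLabels` (per particle), `mergeMap`, `eis`,
#'   `classes` (pooled localizations per class), `fusions`.
#' @export
eigenMerge <- function(particles, dm, clusters, C, cfg = NULL, nPix = 400L,
                       blurPx = 0, refineFusion = FALSE) {
  labels <- if (is(clusters, "ClusterResult")) clusters@labels else
    as.integer(clusters)
  K <- max(labels)
  if (is.null(cfg))
    cfg <- registrationConfig(scale = dm@scale, pixelNm = dm@pixelNm)
  fusions <- lapply(seq_len(K), function(k)
    fuseCluster(particles, dm, which(labels == k), refine = refineFusion,
                cfg = cfg))
  al <- alignClusters(fusions, cfg)
  extent <- sharedExtent(al$aligned)
  imgs <- lapply(al$aligned, renderImage, nPix = nPix, extent = extent,
                 blurPx = blurPx)
  eis <- eigenImages(imgs, extent = extent)
  pm <- projectAndMerge(eis, C, aligned = al$aligned)
  list(classLabels = pm$mergeMap[labels], mergeMap = pm$mergeMap,
       eis = pm$eis, classes = pm$classes, fusions = fusions,
       alignment = al)
}
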