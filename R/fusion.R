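# Per-cluster particle fusion.
#
# A full transform-graph-averaging fusion is out of scope here: the member
# with the highest mean similarity to the other members is chosen as the
# reference frame, every member is mapped into it with the transform already
# found by the all-to-all registration, and the localizations are pooled.
# Optionally each member is re-registered once against the pooled cloud. The
# interface is deliberately small so a heavier fusion can be swapped in.

#' Fuse the particles of one cluster
#'
#' @param particles [ParticleSet-class] or list of [LocalizationSet-class]
#'   (the full set the dissimilarity matrix was computed on).
#' @param dm the [DissimilarityMatrix-class] from [allToAll()].
#' @param members integer indices of the cluster members.
#' @param refine if `TRUE`, each member is re-registered once against the
#'   pooled cloud of the remaining members.
#' @param cfg [RegistrationConfig-class] used for the refinement pass.
#' @return A [FusedReconstruction-class]. The pooled localization count
#'   equals the sum of the member counts.
#' @export
fuseCluster <- function(particles, dm, members, refine = FALSE,
                        cfg = NULL) {
  plist <- .asParticleList(particles)
  members <- as.integer(members)
  if (!length(members)) stop("at least one member required")
  if (max(members) > nrow(dm@D) || min(members) < 1L)
    stop("member index outside the dissimilarity matrix")
  d <- ncol(plist[[1]]@coords)

  if (length(members) == 1L) {
    p <- plist[[members]]
    return(new("FusedReconstruction", locs = p,
               memberIds = p@id, reference = p@id,
               transforms = list(identityTransform(d))))
  }
  # reference: member with maximal mean similarity to the other members,
  # ties broken by lowest index
  Ssub <- dm@S[members, members, drop = FALSE]
  diag(Ssub) <- NA
  meanS <- rowMeans(Ssub, na.rm = TRUE)
  ref <- members[which.max(meanS)]

  transforms <- vector("list", length(members))
  pooledCoords <- vector("list", length(members))
  for (k in seq_along(members)) {
    m <- members[k]
    tr <- if (m == ref) identityTransform(d) else pairTransform(dm, ref, m)
    transforms[[k]] <- tr
    pooledCoords[[k]] <- applyTransform(tr, plist[[m]]@coords)
  }

  if (isTRUE(refine)) {
    if (is.null(cfg)) cfg <- registrationConfig(scale = dm@scale,
                                                pixelNm = dm@pixelNm)
    for (k in seq_along(members)) {
      others <- do.call(rbind, pooledCoords[-k])
      sigOthers <- unlist(lapply(members[-k], function(m) plist[[m]]@sigma))
      pooled <- LocalizationSet(others, sigOthers, id = "pooled")
      r <- registerPair(pooled, plist[[members[k]]], cfg)
      transforms[[k]] <- r$transform
      pooledCoords[[k]] <- applyTransform(r$transform,
                                          plist[[members[k]]]@coords)
    }
  }

  coords <- do.call(rbind, pooledCoords)
  sigma <- unlist(lapply(members, function(m) plist[[m]]@sigma))
  sigmaZ <- unlist(lapply(members, function(m) plist[[m]]@sigmaZ))
  ids <- vapply(members, function(m) plist[[m]]@id, character(1))
  refId <- plist[[ref]]@id
  new("FusedReconstruction",
      locs = LocalizationSet(coords, sigma, sigmaZ %||% numeric(0),
                             id = sprintf("fusion(%s)", refId)),
      memberIds = ids, reference = refId, transforms = transforms)
}

#' Density-based clustering of localizations (DBSCAN)
#'
#' Plain O(n^2) DBSCAN. Points with at least `minPts` neighbors within `eps`
#' (the point itself included) are core points; clusters are the connected
#' components of core points plus their border points; remaining points are
#' noise (label 0).
#'
#' @param coords numeric matrix of positions.
#' @param eps neighborhood radius (same units as `coords`).
#' @param minPts minimum number of points (self included) for a core point.
#' @return Integer labels; 0 marks noise.
#' @export
dbscanPoints <- function(coords, eps, minPts = 4L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  dx <- as.matrix(dist(coords))
  nb <- lapply(seq_len(n), function(i) which(dx[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= minPts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      q <- queue[1]
      queue <- queue[-1]
      for (j in nb[[q]]) {
        if (labels[j] == 0L) {
          labels[j] <- cl
          if (core[j]) queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

#' Fuse a cluster of regular grid-like structures
#'
#' For structures with regular, symmetric binding-site patterns, raw-cloud
#' fusion is suboptimal when the localization counts per site are unbalanced.
#' Here each member's localizations are first grouped into binding sites by
#' DBSCAN (defaults: eps 0.03 camera pixels, 4 points minimum); each site is
#' replaced by its center with the mean site uncertainty; registration and
#' fusion run on the site centers; finally the centers are replaced by all
#' original localizations, so the pooled count equals the input count.
#'
#' @param particles full particle set ([ParticleSet-class] or list).
#' @param members integer indices of the cluster members.
#' @param cfg [RegistrationConfig-class] for the center registration; its
#'   `pixelNm` converts `eps` to nm.
#' @param eps DBSCAN radius in camera pixels.
#' @param minPts DBSCAN minimum points per site.
#' @return A [FusedReconstruction-class] on the original localizations.
#' @export
fuseGridStructure <- function(particles, members,
                              cfg = registrationConfig(scale = 0.03),
                              eps = 0.03, minPts = 4L) {
  plist <- .asParticleList(particles)
  members <- as.integer(members)
  epsNm <- eps * cfg@pixelNm
  centers <- vector("list", length(members))
  for (k in seq_along(members)) {
    p <- plist[[members[k]]]
    lab <- dbscanPoints(p@coords, epsNm, minPts)
    if (all(lab == 0L)) {
      warning(sprintf("particle %s: no DBSCAN site found; using raw cloud",
                      p@id))
      centers[[k]] <- p
      next
    }
    cl <- sort(unique(lab[lab > 0L]))
    cc <- t(vapply(cl, function(g)
      colMeans(p@coords[lab == g, , drop = FALSE]),
      numeric(ncol(p@coords))))
    cs <- vapply(cl, function(g) mean(p@sigma[lab == g]), numeric(1))
    csz <- if (length(p@sigmaZ))
      vapply(cl, function(g) mean(p@sigmaZ[lab == g]), numeric(1))
    else numeric(0)
    centers[[k]] <- LocalizationSet(cc, cs, csz, id = p@id)
  }
  if (length(members) == 1L) {
    p <- plist[[members]]
    return(new("FusedReconstruction", locs = p, memberIds = p@id,
               reference = p@id,
               transforms = list(identityTransform(ncol(p@coords)))))
  }
  dmC <- allToAll(centers, cfg)
  fusedC <- fuseCluster(centers, dmC, seq_along(members))
  # replace centers by the original localizations under the same transforms
  coords <- do.call(rbind, lapply(seq_along(members), function(k)
    applyTransform(fusedC@transforms[[k]], plist[[members[k]]]@coords)))
  sigma <- unlist(lapply(members, function(m) plist[[m]]@sigma))
  sigmaZ <- unlist(lapply(members, function(m) plist[[m]]@sigmaZ))
  new("FusedReconstruction",
      locs = LocalizationSet(coords, sigma, sigmaZ %||% numeric(0),
                             id = sprintf("gridFusion(%s)",
                                          fusedC@reference)),
      memberIds = vapply(members, function(m) plist[[m]]@id, character(1)),
      reference = fusedC@reference, transforms = fusedC@transforms)
}
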