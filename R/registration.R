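# Pairwise rigid registration and the all-to-all dissimilarity matrix.
#
# The registration objective is the overlap of two Gaussian mixtures in which
# every localization carries the same width ("scale", quoted in camera
# pixels); the reported similarity is the Bhattacharyya score, which
# normalizes by the localization counts and by the per-pair uncertainty sums:
#
#   S(a,b) = 1/(Ka*Kb) * sum_i sum_j exp(-0.5*|r_ai - T(r_bj)|^2 /
#            (sigma_ai^2 + sigma_bj^2)) / (sigma_ai^2 + sigma_bj^2)
#
# Each pair is optimized from several rotation starts; the Bhattacharyya
# score is evaluated at every local optimum and the best-scoring transform
# wins.

#' Registration settings
#'
#' @param scale GMM kernel width in camera pixels; `NA` means determine it
#'   with [scaleSweep()] before registering.
#' @param pixelNm camera pixel size in nm.
#' @param nAngleInits number of uniformly spaced rotation starts (2D).
#' @param maxEvalCoarse simplex evaluation budget per start (pose search runs
#'   on clouds subsampled to `maxLocsOptim` localizations).
#' @param maxEvalRefine evaluation budget of one full-cloud refinement of the
#'   winning start (0 disables).
#' @param ftol relative objective tolerance of the simplex.
#' @param maxLocsOptim localization cap per particle during the pose search;
#'   scoring and refinement always use the full clouds.
#' @param minLocsOptim particles below this size skip pose optimization (a
#'   3-parameter pose is under-determined below 3 points); such pairs are
#'   scored at the identity transform.
#' @param nInPlane3D in-plane start angles per icosahedral axis (3D pose
#'   search uses 12 axes x `nInPlane3D` starts).
#' @return A [RegistrationConfig-class].
#' @export
registrationConfig <- function(scale = NA_real_, pixelNm = 130,
                               nAngleInits = 6L, maxEvalCoarse = 60L,
                               maxEvalRefine = 60L, ftol = 1e-4,
                               maxLocsOptim = 20L, minLocsOptim = 3L,
                               nInPlane3D = 4L) {
  new("RegistrationConfig", scale = as.numeric(scale),
      pixelNm = as.numeric(pixelNm), nAngleInits = as.integer(nAngleInits),
      maxEvalCoarse = as.integer(maxEvalCoarse),
      maxEvalRefine = as.integer(maxEvalRefine), ftol = as.numeric(ftol),
      maxLocsOptim = as.integer(maxLocsOptim),
      minLocsOptim = as.integer(minLocsOptim),
      nInPlane3D = as.integer(nInPlane3D))
}

.asParticleList <- function(particles) {
  if (is(particles, "ParticleSet")) particles <- particles@particles
  if (is(particles, "LocalizationSet")) particles <- list(particles)
  stopifnot(all(vapply(particles, is, logical(1), "LocalizationSet")))
  particles
}

.checkPairDims <- function(a, b) {
  if (ncol(a@coords) != ncol(b@coords))
    stop("particles have different dimensionality")
  ncol(a@coords)
}

#' Bhattacharyya similarity between two localization clouds
#'
#' Normalized overlap of the two clouds treated as Gaussian mixtures with
#' per-localization widths: the sum over all localization pairs of
#' `exp(-0.5 r^2 / (sigma_a^2 + sigma_b^2)) / (sigma_a^2 + sigma_b^2)`,
#' divided by `Ka * Kb`. In 3D with separate axial uncertainties the variance
#' sums enter the exponent per axis and the prefactor uses the geometric mean
#' of the per-axis variance sums.
#'
#' @param a,b [LocalizationSet-class] objects of equal dimensionality.
#' @param transform `rigidTransform` applied to `b` (default identity).
#' @return The similarity score (non-negative scalar).
#' @examples
#' p <- LocalizationSet(cbind(0, 0), sigma = 1)
#' bhattacharyyaScore(p, p)  # 1/(1+1) * exp(0) = 0.5
#' @export
bhattacharyyaScore <- function(a, b, transform = NULL) {
  d <- .checkPairDims(a, b)
  if (is.null(transform)) transform <- identityTransform(d)
  if (transform$dim != d) stop("transform dimensionality mismatch")
  cppBhatScore(a@coords, a@sigma, a@sigmaZ, b@coords, b@sigma, b@sigmaZ,
               transform$R, transform$t)
}

#' Gaussian-mixture overlap (registration objective)
#'
#' Exact overlap integral of the two clouds rendered as Gaussian mixtures in
#' which every component has the same width `scale` (localization
#' uncertainties are deliberately ignored here; they enter only the
#' Bhattacharyya score).
#'
#' @param a,b [LocalizationSet-class] objects.
#' @param scale kernel width in camera pixels.
#' @param transform `rigidTransform` applied to `b` (default identity).
#' @param pixelNm camera pixel size in nm.
#' @return The overlap value.
#' @export
gmmOverlap <- function(a, b, scale, transform = NULL, pixelNm = 130) {
  if (scale <= 0) stop("scale must be > 0")
  d <- .checkPairDims(a, b)
  if (is.null(transform)) transform <- identityTransform(d)
  cppGmmOverlap(a@coords, b@coords, scale * pixelNm, transform$R,
                transform$t)
}

#' Register one particle pair
#'
#' Starting from `nAngleInits` rotations (2D; icosahedral axis x in-plane
#' starts in 3D), locally maximizes the GMM overlap over rigid transforms
#' with a derivative-free simplex, evaluates the Bhattacharyya score at every
#' local optimum (full clouds), refines the winner once on the full clouds,
#' and returns the best-scoring transform.
#'
#' @param a,b [LocalizationSet-class] objects.
#' @param cfg a [RegistrationConfig-class]; `cfg@scale` must be set.
#' @return A list: `transform` (maps `b` into the frame of `a`), `S` (best
#'   Bhattacharyya score), `gmm` (objective at the optimum),
#'   `nStartsConverged`, and `perStart` (2D: per-start transforms and
#'   scores).
#' @examples
#' set.seed(2)
#' a <- sampleParticle(makeTemplate("dots", letter = "L"), acquisitionModel())
#' b <- sampleParticle(makeTemplate("dots", letter = "L"), acquisitionModel())
#' registerPair(a, b, registrationConfig(scale = 0.05))$S
#' @export
registerPair <- function(a, b, cfg = registrationConfig(scale = 0.1)) {
  d <- .checkPairDims(a, b)
  if (is.na(cfg@scale))
    stop("cfg@scale is not set; run scaleSweep() or supply a scale")
  scaleNm <- cfg@scale * cfg@pixelNm
  doOpt <- nLocs(a) >= cfg@minLocsOptim && nLocs(b) >= cfg@minLocsOptim
  if (d == 2L) {
    angles <- 2 * pi * (seq_len(cfg@nAngleInits) - 1) / cfg@nAngleInits
    r <- cppRegisterPair2D(a@coords, a@sigma, b@coords, b@sigma, scaleNm,
                           angles, cfg@maxEvalCoarse, cfg@maxEvalRefine,
                           cfg@ftol, cfg@maxLocsOptim, doOpt)
    tr <- rigidTransform(theta = r$theta, t = c(r$tx, r$ty))
  } else {
    inits <- icosahedronRotations(cfg@nInPlane3D)
    r <- cppRegisterPair3D(a@coords, a@sigma, a@sigmaZ, b@coords, b@sigma,
                           b@sigmaZ, scaleNm, inits, cfg@maxEvalCoarse,
                           cfg@maxEvalRefine, cfg@ftol, cfg@maxLocsOptim,
                           doOpt)
    tr <- rigidTransform(R = r$R, t = r$t)
  }
  if (doOpt && r$nStartsConverged == 0L)
    warning("no optimizer start converged; returning best evaluated transform")
  list(transform = tr, S = r$S, gmm = r$gmm,
       nStartsConverged = r$nStartsConverged, perStart = r$perStart)
}

#' Determine the GMM scale by a sweep
#'
#' Registers `nPairs` randomly sampled particle pairs at `nScales` scales
#' linearly spaced over `range` (camera pixels; 0.001-0.5 px is 0.13-65 nm at
#' 130 nm/px). Each pair's curve of achieved GMM values is normalized to its
#' maximum and the curves are averaged; the scale at the maximum of the mean
#' curve is returned.
#'
#' @param particles a [ParticleSet-class] or list of
#'   [LocalizationSet-class].
#' @param nPairs number of random pairs.
#' @param nScales number of scales.
#' @param range sweep range in camera pixels.
#' @param cfg [RegistrationConfig-class] (its scale field is ignored).
#' @param seed seed for the pair sampling.
#' @return The selected scale (camera pixels), with the sweep table in
#'   attribute `sweep`.
#' @export
scaleSweep <- function(particles, nPairs = 10L, nScales = 50L,
                       range = c(0.001, 0.5), cfg = registrationConfig(),
                       seed = NULL) {
  particles <- .asParticleList(particles)
  N <- length(particles)
  if (N < 2L) stop("scale sweep needs at least 2 particles")
  scales <- seq(range[1], range[2], length.out = nScales)
  pairs <- withSeed(seed, {
    t(replicate(nPairs, sample.int(N, 2L)))
  })
  vals <- matrix(NA_real_, nPairs, nScales)
  for (p in seq_len(nPairs)) {
    a <- particles[[pairs[p, 1]]]
    b <- particles[[pairs[p, 2]]]
    for (s in seq_len(nScales)) {
      cfgS <- cfg
      cfgS@scale <- scales[s]
      r <- registerPair(a, b, cfgS)
      vals[p, s] <- gmmOverlap(a, b, scales[s], r$transform, cfg@pixelNm)
    }
    vals[p, ] <- vals[p, ] / max(vals[p, ])
  }
  curve <- colMeans(vals)
  out <- scales[which.max(curve)]
  attr(out, "sweep") <- data.frame(scale = scales, meanOverlap = curve)
  out
}

#' All-to-all registration and dissimilarity matrix
#'
#' Registers all N(N-1)/2 unordered particle pairs with [registerPair()]'s
#' procedure, collects the optimal Bhattacharyya scores S and converts them
#' to dissimilarities D = max(S) - S (max over off-diagonal entries), so the
#' best-matching pair has D = 0. The per-pair optimal transforms are stored
#' for the fusion stage. Pair computations are independent of each other and
#' of their order.
#'
#' @param particles a [ParticleSet-class] or list of
#'   [LocalizationSet-class].
#' @param cfg a [RegistrationConfig-class]; if `cfg@scale` is `NA`, a
#'   [scaleSweep()] is run first (seeded with `sweepSeed`).
#' @param sweepSeed seed for the scale sweep's pair sampling.
#' @return A [DissimilarityMatrix-class].
#' @export
allToAll <- function(particles, cfg = registrationConfig(), sweepSeed = 1L) {
  plist <- .asParticleList(particles)
  N <- length(plist)
  if (N < 2L) stop("all-to-all registration needs at least 2 particles")
  d <- ncol(plist[[1]]@coords)
  if (is.na(cfg@scale))
    cfg@scale <- as.numeric(scaleSweep(plist, cfg = cfg, seed = sweepSeed))
  scaleNm <- cfg@scale * cfg@pixelNm
  coordsL <- lapply(plist, function(p) p@coords)
  sigmaL <- lapply(plist, function(p) p@sigma)
  if (d == 2L) {
    res <- cppAllPairs2D(coordsL, sigmaL, scaleNm, cfg@nAngleInits,
                         cfg@maxEvalCoarse, cfg@maxEvalRefine, cfg@ftol,
                         cfg@maxLocsOptim, cfg@minLocsOptim)
  } else {
    sigmaZL <- lapply(plist, function(p) p@sigmaZ)
    inits <- icosahedronRotations(cfg@nInPlane3D)
    res <- cppAllPairs3D(coordsL, sigmaL, sigmaZL, scaleNm, inits,
                         cfg@maxEvalCoarse, cfg@maxEvalRefine, cfg@ftol,
                         cfg@maxLocsOptim, cfg@minLocsOptim)
  }
  S <- res$S
  off <- S
  diag(off) <- -Inf
  D <- max(off) - S
  diag(D) <- 0
  ids <- vapply(plist, function(p) p@id, character(1))
  if (anyNA(ids) || anyDuplicated(ids))
    ids <- sprintf("p%04d", seq_len(N))
  dimnames(S) <- dimnames(D) <- list(ids, ids)
  new("DissimilarityMatrix", S = S, D = D, transformParams = res$params,
      dims = as.integer(d), scale = cfg@scale, pixelNm = cfg@pixelNm,
      particleIds = ids, nStartsConverged = as.integer(res$nStartsConverged))
}

#' @rdname pairTransform
#' @export
setMethod("pairTransform", "DissimilarityMatrix", function(x, i, j) {
  N <- nrow(x@D)
  k <- pairIndex(i, j, N)
  p <- x@transformParams[k, ]
  tr <- if (x@dims == 2L) {
    rigidTransform(theta = p[1], t = p[2:3])
  } else {
    rigidTransform(R = matrix(p[1:9], 3, 3), t = p[10:12])
  }
  if (i < j) tr else invertTransform(tr)
})
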