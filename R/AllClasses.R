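# S4 containers for the classification pipeline.

#' LocalizationSet: one particle's localization cloud
#'
#' Coordinates are in nm. `sigma` holds one (lateral, isotropic) localization
#' uncertainty per localization; for 3D data an optional separate axial
#' uncertainty `sigmaZ` may be supplied, otherwise `sigma` is treated as
#' isotropic in all three dimensions.
#'
#' @slot coords numeric matrix, n x 2 or n x 3, localization positions (nm).
#' @slot sigma numeric, length n, per-localization lateral uncertainty (nm).
#' @slot sigmaZ numeric, length 0 (isotropic) or n, axial uncertainty (nm).
#' @slot id character(1), particle identifier.
#' @export
setClass("LocalizationSet",
  representation(coords = "matrix", sigma = "numeric", sigmaZ = "numeric",
                 id = "character"),
  prototype(coords = matrix(0, 1, 2), sigma = 1, sigmaZ = numeric(0),
            id = NA_character_))

setValidity("LocalizationSet", function(object) {
  n <- nrow(object@coords)
  d <- ncol(object@coords)
  if (n < 1L) return("at least one localization required")
  if (!d %in% c(2L, 3L)) return("coords must have 2 or 3 columns")
  if (!all(is.finite(object@coords))) return("coords must be finite")
  if (length(object@sigma) != n) return("sigma must have one value per localization")
  if (!all(is.finite(object@sigma)) || any(object@sigma <= 0))
    return("all sigma must be finite and > 0")
  if (length(object@sigmaZ) > 0L) {
    if (d != 3L) return("sigmaZ only allowed for 3D coordinates")
    if (length(object@sigmaZ) != n) return("sigmaZ must have one value per localization")
    if (!all(is.finite(object@sigmaZ)) || any(object@sigmaZ <= 0))
      return("all sigmaZ must be finite and > 0")
  }
  if (length(object@id) != 1L) return("id must be a single string")
  TRUE
})

#' Construct a LocalizationSet
#'
#' @param coords numeric matrix (n x 2 or n x 3) of positions in nm.
#' @param sigma per-localization lateral uncertainty in nm (recycled if
#'   length 1).
#' @param sigmaZ optional per-localization axial uncertainty in nm (3D only).
#' @param id particle identifier.
#' @return A [LocalizationSet-class] object.
#' @examples
#' p <- LocalizationSet(cbind(c(0, 20), c(0, 0)), sigma = 2)
#' nLocs(p)
#' @export
LocalizationSet <- function(coords, sigma, sigmaZ = numeric(0),
                            id = NA_character_) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(sigma) == 1L) sigma <- rep(as.numeric(sigma), nrow(coords))
  if (length(sigmaZ) == 1L) sigmaZ <- rep(as.numeric(sigmaZ), nrow(coords))
  new("LocalizationSet", coords = coords, sigma = as.numeric(sigma),
      sigmaZ = as.numeric(sigmaZ), id = as.character(id))
}

#' ParticleSet: a collection of particles with optional ground-truth labels
#'
#' @slot particles list of [LocalizationSet-class] objects.
#' @slot trueClass integer vector of ground-truth class labels (possibly NA).
#' @slot templateNames character vector naming the mixture components that
#'   generated each class (empty for experimental data).
#' @slot poses list of the ground-truth `rigidTransform` poses (empty for
#'   loaded data); useful for validating registration and fusion.
#' @slot seed integer(1), the seed the dataset was generated from (NA for
#'   loaded data).
#' @export
setClass("ParticleSet",
  representation(particles = "list", trueClass = "integer",
                 templateNames = "character", poses = "list",
                 seed = "integer"),
  prototype(particles = list(), trueClass = integer(0),
            templateNames = character(0), poses = list(),
            seed = NA_integer_))

setValidity("ParticleSet", function(object) {
  if (!all(vapply(object@particles, is, logical(1), "LocalizationSet")))
    return("all particles must be LocalizationSet objects")
  if (length(object@trueClass) > 0L &&
      length(object@trueClass) != length(object@particles))
    return("trueClass must be empty or match the number of particles")
  if (length(object@particles) > 1L) {
    d <- vapply(object@particles, function(p) ncol(p@coords), integer(1))
    if (length(unique(d)) != 1L)
      return("all particles must have the same dimensionality")
  }
  TRUE
})

#' SiteTemplate: designed binding-site geometry of a structure
#'
#' @slot coords numeric matrix of site positions (nm), centered at origin.
#' @slot name template identifier.
#' @slot symmetryFold integer rotational symmetry fold (NA if none).
#' @export
setClass("SiteTemplate",
  representation(coords = "matrix", name = "character",
                 symmetryFold = "integer"),
  prototype(symmetryFold = NA_integer_))

setValidity("SiteTemplate", function(object) {
  if (nrow(object@coords) < 2L) return("a template needs at least 2 sites")
  if (!ncol(object@coords) %in% c(2L, 3L))
    return("site coords must be 2D or 3D")
  if (!all(is.finite(object@coords))) return("site coords must be finite")
  dd <- dist(object@coords)
  if (any(dd <= 0)) return("all pairwise site distances must be > 0")
  TRUE
})

#' AcquisitionModel: statistical model of the imaging process
#'
#' @slot dol density of labeling: probability in (0, 1] that a binding site
#'   carries a functional label.
#' @slot locsPerSite mean number of localizations emitted per labeled site.
#' @slot locsDist `"poisson"` (counts ~ Poisson(locsPerSite)) or `"fixed"`
#'   (exactly `locsPerSite` localizations per labeled site).
#' @slot sigmaMeanNm mean of the Gamma distribution of lateral localization
#'   uncertainties (nm).
#' @slot sigmaShape Gamma shape parameter of the uncertainty distribution.
#' @slot sigmaZMeanNm mean axial uncertainty for 3D data (nm).
#' @slot pixelNm camera pixel size in nm.
#' @export
setClass("AcquisitionModel",
  representation(dol = "numeric", locsPerSite = "numeric",
                 locsDist = "character", sigmaMeanNm = "numeric",
                 sigmaShape = "numeric", sigmaZMeanNm = "numeric",
                 pixelNm = "numeric"))

setValidity("AcquisitionModel", function(object) {
  if (object@dol <= 0 || object@dol > 1) return("dol must be in (0, 1]")
  if (object@locsPerSite <= 0) return("locsPerSite mean must be > 0")
  if (!object@locsDist %in% c("poisson", "fixed"))
    return("locsDist must be 'poisson' or 'fixed'")
  if (object@sigmaMeanNm <= 0 || object@sigmaShape <= 0)
    return("sigma distribution parameters must be > 0")
  if (object@sigmaZMeanNm <= 0) return("sigmaZMeanNm must be > 0")
  if (object@pixelNm <= 0) return("pixelNm must be > 0")
  TRUE
})

#' MixtureSpec: composition of a synthetic dataset
#'
#' @slot components list; each element a list with fields `template`
#'   ([SiteTemplate-class]), `fraction`, `mirror` (logical), `deformation`
#'   (ellipticity, major/minor axis ratio applied as area-preserving
#'   anisotropic scaling) and `zScale`.
#' @slot nParticles total particle count.
#' @slot seed integer seed making the dataset reproducible.
#' @export
setClass("MixtureSpec",
  representation(components = "list", nParticles = "integer",
                 seed = "integer"))

setValidity("MixtureSpec", function(object) {
  if (length(object@components) < 1L) return("at least one component required")
  fr <- vapply(object@components, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8) return("component fractions must sum to 1")
  if (any(fr < 0)) return("fractions must be non-negative")
  defo <- vapply(object@components, `[[`, numeric(1), "deformation")
  zs <- vapply(object@components, `[[`, numeric(1), "zScale")
  if (any(!is.finite(defo)) || any(defo <= 0) || any(!is.finite(zs)) ||
      any(zs <= 0))
    return("deformation and zScale must be finite and > 0")
  if (object@nParticles < 1L) return("nParticles must be >= 1")
  if (is.na(object@seed)) return("a seed is required")
  TRUE
})

#' RegistrationConfig: settings of the pairwise registration
#'
#' @slot scale GMM kernel width in camera pixels (NA = determine by
#'   [scaleSweep()]).
#' @slot pixelNm camera pixel size in nm (converts `scale` to nm).
#' @slot nAngleInits number of rotation initializations (2D).
#' @slot maxEvalCoarse objective-evaluation budget per initialization.
#' @slot maxEvalRefine evaluation budget of the full-cloud refinement of the
#'   winning initialization (0 disables refinement).
#' @slot ftol relative objective tolerance of the simplex optimizer.
#' @slot maxLocsOptim localization cap per particle during the pose search
#'   (full clouds are always used for scoring and refinement).
#' @slot minLocsOptim pairs in which either particle has fewer localizations
#'   skip optimization and are scored at the identity transform.
#' @slot nInPlane3D in-plane angles per icosahedral axis initialization (3D).
#' @export
setClass("RegistrationConfig",
  representation(scale = "numeric", pixelNm = "numeric",
                 nAngleInits = "integer", maxEvalCoarse = "integer",
                 maxEvalRefine = "integer", ftol = "numeric",
                 maxLocsOptim = "integer", minLocsOptim = "integer",
                 nInPlane3D = "integer"))

setValidity("RegistrationConfig", function(object) {
  if (!is.na(object@scale) && object@scale <= 0) return("scale must be > 0")
  if (object@pixelNm <= 0) return("pixelNm must be > 0")
  if (object@nAngleInits < 1L) return("nAngleInits must be >= 1")
  if (object@maxEvalCoarse < 10L) return("maxEvalCoarse must be >= 10")
  if (object@maxEvalRefine < 0L) return("maxEvalRefine must be >= 0")
  if (object@ftol <= 0) return("ftol must be > 0")
  if (object@maxLocsOptim < 3L) return("maxLocsOptim must be >= 3")
  if (object@minLocsOptim < 1L) return("minLocsOptim must be >= 1")
  if (object@nInPlane3D < 1L) return("nInPlane3D must be >= 1")
  TRUE
})

#' DissimilarityMatrix: all-to-all registration result
#'
#' Holds the symmetric similarity matrix S (optimal Bhattacharyya score per
#' pair; the diagonal stores the identity self-score as a diagnostic), the
#' dissimilarity D = max(S) - S (maximum over off-diagonal entries, diagonal
#' set to 0), and the optimal rigid transform of every pair, which the fusion
#' stage reuses.
#'
#' @slot S numeric matrix, N x N similarity values.
#' @slot D numeric matrix, N x N dissimilarities.
#' @slot transformParams numeric matrix with one row per unordered pair
#'   (i < j, row-major over i), mapping particle j into the frame of i:
#'   columns (theta, tx, ty) in 2D or 9 rotation-matrix entries
#'   (column-major) plus 3 translation entries in 3D.
#' @slot dims spatial dimensionality (2 or 3).
#' @slot scale GMM scale used, in camera pixels.
#' @slot pixelNm camera pixel size (nm).
#' @slot particleIds particle identifiers.
#' @slot nStartsConverged per-pair count of converged optimizer starts.
#' @export
setClass("DissimilarityMatrix",
  representation(S = "matrix", D = "matrix", transformParams = "matrix",
                 dims = "integer", scale = "numeric", pixelNm = "numeric",
                 particleIds = "character", nStartsConverged = "integer"))

setValidity("DissimilarityMatrix", function(object) {
  N <- nrow(object@D)
  if (ncol(object@D) != N || nrow(object@S) != N || ncol(object@S) != N)
    return("S and D must be square matrices of equal size")
  if (max(abs(object@D - t(object@D))) > 1e-9) return("D must be symmetric")
  if (any(object@D < -1e-12)) return("all dissimilarities must be >= 0")
  if (any(abs(diag(object@D)) > 1e-12)) return("D diagonal must be 0")
  off <- object@D[upper.tri(object@D)]
  if (N > 1L && min(off) > 1e-9 * max(1, max(off)))
    return("the best-matching pair must have dissimilarity 0")
  TRUE
})

#' MDSEmbedding: metric MDS coordinates of the particles
#'
#' @slot coords N x d embedding coordinates.
#' @slot stress achieved normalized metric stress.
#' @slot trace stress value per majorization iteration.
#' @slot converged whether the relative stress change fell below tolerance.
#' @export
setClass("MDSEmbedding",
  representation(coords = "matrix", stress = "numeric", trace = "numeric",
                 converged = "logical"))

setValidity("MDSEmbedding", function(object) {
  if (!all(is.finite(object@coords))) return("embedding must be finite")
  if (object@stress < 0) return("stress must be >= 0")
  TRUE
})

#' ClusterResult: k-means labels with restart diagnostics and silhouettes
#'
#' @slot labels integer cluster labels in 1..K.
#' @slot K number of clusters.
#' @slot totWithinSS total within-cluster sum of squared point-to-centroid
#'   distances of the best restart.
#' @slot silhouette per-particle silhouette values (NA if not computed).
#' @slot meanSilhouette mean silhouette over all particles.
#' @slot silhouetteDims number of leading embedding dimensions the
#'   silhouette was computed on.
#' @slot nRestarts number of k-means restarts performed.
#' @slot nFailedRestarts restarts that failed (degenerate initial centers).
#' @export
setClass("ClusterResult",
  representation(labels = "integer", K = "integer", totWithinSS = "numeric",
                 silhouette = "numeric", meanSilhouette = "numeric",
                 silhouetteDims = "integer", nRestarts = "integer",
                 nFailedRestarts = "integer"))

setValidity("ClusterResult", function(object) {
  if (any(object@labels < 1L) || any(object@labels > object@K))
    return("labels must lie in 1..K")
  if (length(unique(object@labels)) != object@K)
    return("all K clusters must be non-empty")
  sil <- object@silhouette[!is.na(object@silhouette)]
  if (length(sil) && (min(sil) < -1 - 1e-12 || max(sil) > 1 + 1e-12))
    return("silhouette values must lie in [-1, 1]")
  TRUE
})

#' FusedReconstruction: pooled localizations of one cluster
#'
#' @slot locs pooled [LocalizationSet-class] in the reference frame.
#' @slot memberIds identifiers of the fused member particles.
#' @slot reference id of the member chosen as reference frame.
#' @slot transforms list of rigid transforms (one per member) that mapped
#'   each member into the reference frame.
#' @export
setClass("FusedReconstruction",
  representation(locs = "LocalizationSet", memberIds = "character",
                 reference = "character", transforms = "list"))

#' EigenImageSet: eigen-image decomposition of rendered cluster images
#'
#' @slot images nPix x nPix x K array of normalized cluster renderings
#'   (each zero mean, unit 2-norm).
#' @slot eigenImages nPix x nPix x K array of eigen images.
#' @slot singularValues singular values, non-increasing.
#' @slot weights projections of the K images onto the first eigen image.
#' @slot mergeMap integer K -> C assignment (length 0 before merging).
#' @slot extent shared rendering frame c(xmin, xmax, ymin, ymax) in nm.
#' @slot nPix image side length in pixels.
#' @export
setClass("EigenImageSet",
  representation(images = "array", eigenImages = "array",
                 singularValues = "numeric", weights = "numeric",
                 mergeMap = "integer", extent = "numeric", nPix = "integer"))

setValidity("EigenImageSet", function(object) {
  sv <- object@singularValues
  if (is.unsorted(rev(sv), strictly = FALSE)) {
    if (any(diff(sv) > 1e-8 * max(sv))) return("singular values must be non-increasing")
  }
  K <- dim(object@images)[3]
  if (length(object@mergeMap) > 0L && length(object@mergeMap) != K)
    return("mergeMap must assign every cluster")
  TRUE
})

#' EllipseFit: ellipse fitted to a ring-like structure
#'
#' @slot center ellipse center (nm).
#' @slot a semi-major axis (nm).
#' @slot b semi-minor axis (nm).
#' @slot theta orientation of the major axis vs the x-axis, in [0, pi).
#' @slot e ellipticity a/b (>= 1).
#' @export
setClass("EllipseFit",
  representation(center = "numeric", a = "numeric", b = "numeric",
                 theta = "numeric", e = "numeric"))

setValidity("EllipseFit", function(object) {
  if (object@b <= 0 || object@a < object@b) return("need a >= b > 0")
  if (object@theta < 0 || object@theta >= pi) return("theta must be in [0, pi)")
  if (abs(object@e - object@a / object@b) > 1e-9) return("e must equal a/b")
  TRUE
})
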