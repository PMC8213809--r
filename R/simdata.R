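# Synthetic SMLM particle generator.
#
# Emulates the data the classification pipeline assumes: designed binding-site
# templates observed under underlabeling (density of labeling, DoL), several
# localizations per labeled site, Gaussian localization noise with a
# per-localization uncertainty, random in-plane pose, optional mirroring and
# optional elliptical deformation.

# letter-like dot patterns (unit pitch; scaled by `pitch` in makeTemplate)
.letterDots <- list(
  T = rbind(c(-2, 2), c(-1, 2), c(0, 2), c(1, 2), c(2, 2),
            c(0, 1), c(0, 0), c(0, -1), c(0, -2)),
  O = rbind(c(-1, 2), c(0, 2), c(1, 2), c(-1, -2), c(0, -2), c(1, -2),
            c(-1, 1), c(-1, 0), c(-1, -1), c(1, 1), c(1, 0), c(1, -1)),
  L = rbind(c(-1, 2), c(-1, 1), c(-1, 0), c(-1, -1), c(-1, -2),
            c(0, -2), c(1, -2))
)

#' Create a binding-site template
#'
#' Builds the designed site geometry of a structure, centered at the origin.
#' Available kinds:
#' \describe{
#'   \item{grid}{`rows` x `cols` lattice with nearest-neighbor distance
#'     `spacing` nm (defaults 3 x 4 at 20 nm: 12 sites).}
#'   \item{ring}{`nFold` sites equally spaced on a circle of `diameter` nm
#'     (default 8 sites on 160 nm, an NPC-like ring with ~60 nm site
#'     spacing).}
#'   \item{dots}{letter-like dot pattern; `letter` one of "T", "O", "L", or
#'     supply explicit `dotCoords` (unit pitch), scaled by `pitch` nm.}
#'   \item{tetrahedron}{4 vertices, base edge `edge` nm, apex `height` nm
#'     above the base (3D).}
#' }
#'
#' @param kind one of `"grid"`, `"ring"`, `"dots"`, `"tetrahedron"`.
#' @param ... geometry parameters of the kind (see Details).
#' @return A [SiteTemplate-class].
#' @examples
#' makeTemplate("grid", rows = 3, cols = 4, spacing = 20)
#' makeTemplate("ring", nFold = 9, diameter = 160)
#' @export
makeTemplate <- function(kind = c("grid", "ring", "dots", "tetrahedron"),
                         ...) {
  kind <- match.arg(kind)
  p <- list(...)
  if (kind == "grid") {
    rows <- p$rows %||% 3L
    cols <- p$cols %||% 4L
    spacing <- p$spacing %||% 20
    if (spacing <= 0) stop("spacing must be > 0")
    xy <- as.matrix(expand.grid(x = (seq_len(cols) - 1) * spacing,
                                y = (seq_len(rows) - 1) * spacing))
    name <- sprintf("grid%dx%d", cols, rows)
    fold <- NA_integer_
  } else if (kind == "ring") {
    nFold <- p$nFold %||% 8L
    diameter <- p$diameter %||% 160
    if (diameter <= 0) stop("diameter must be > 0")
    if (nFold < 2L) stop("nFold must be >= 2")
    ang <- 2 * pi * (seq_len(nFold) - 1) / nFold
    xy <- diameter / 2 * cbind(x = cos(ang), y = sin(ang))
    name <- sprintf("ring%d", nFold)
    fold <- as.integer(nFold)
  } else if (kind == "dots") {
    pitch <- p$pitch %||% 20
    if (pitch <= 0) stop("pitch must be > 0")
    if (!is.null(p$dotCoords)) {
      xy <- as.matrix(p$dotCoords) * pitch
      name <- p$name %||% "dots"
    } else {
      letter <- match.arg(p$letter %||% "T", names(.letterDots))
      xy <- .letterDots[[letter]] * pitch
      name <- paste0("dots", letter)
    }
    colnames(xy) <- c("x", "y")
    fold <- NA_integer_
  } else {
    edge <- p$edge %||% 100
    height <- p$height %||% 90
    if (edge <= 0 || height <= 0) stop("edge and height must be > 0")
    r <- edge / sqrt(3)
    ang <- 2 * pi * (0:2) / 3
    xy <- cbind(x = c(r * cos(ang), 0), y = c(r * sin(ang), 0),
                z = c(0, 0, 0, height))
    name <- "tetrahedron"
    fold <- 3L
  }
  xy <- sweep(xy, 2, colMeans(xy))
  new("SiteTemplate", coords = xy, name = name, symmetryFold = fold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Acquisition model of the simulated imaging process
#'
#' @param dol density of labeling: probability in (0, 1] that a binding site
#'   carries a functional label.
#' @param locsPerSite mean localizations per labeled site.
#' @param locsDist `"poisson"` counts, or `"fixed"` (exactly `locsPerSite`
#'   per labeled site, useful for noise-free checks).
#' @param sigmaMeanNm mean lateral localization uncertainty (nm); individual
#'   uncertainties are Gamma distributed.
#' @param sigmaShape Gamma shape of the uncertainty distribution (larger =
#'   narrower).
#' @param sigmaZMeanNm mean axial uncertainty for 3D templates (nm).
#' @param pixelNm camera pixel size (nm).
#' @return An [AcquisitionModel-class].
#' @export
acquisitionModel <- function(dol = 0.8, locsPerSite = 8,
                             locsDist = c("poisson", "fixed"),
                             sigmaMeanNm = 2, sigmaShape = 4,
                             sigmaZMeanNm = 8, pixelNm = 130) {
  new("AcquisitionModel", dol = dol, locsPerSite = locsPerSite,
      locsDist = match.arg(locsDist), sigmaMeanNm = sigmaMeanNm,
      sigmaShape = sigmaShape, sigmaZMeanNm = sigmaZMeanNm,
      pixelNm = pixelNm)
}

#' Mixture specification of a synthetic dataset
#'
#' @param components list of components; each a list with `template`
#'   ([SiteTemplate-class]) and `fraction`, optionally `mirror` (logical,
#'   reflect about the x-axis before rotation), `deformation` (elliptical
#'   axis ratio e, applied as area-preserving anisotropic scaling sqrt(e) /
#'   1/sqrt(e) before the pose) and `zScale`.
#' @param nParticles total number of particles.
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @return A [MixtureSpec-class].
#' @examples
#' tpl <- makeTemplate("ring")
#' mixtureSpec(list(list(template = tpl, fraction = 1)), 10, seed = 1)
#' @export
mixtureSpec <- function(components, nParticles, seed) {
  components <- lapply(components, function(cm) {
    list(template = cm$template, fraction = cm$fraction,
         mirror = cm$mirror %||% FALSE, deformation = cm$deformation %||% 1,
         zScale = cm$zScale %||% 1)
  })
  new("MixtureSpec", components = components,
      nParticles = as.integer(nParticles), seed = as.integer(seed))
}

#' Simulate the localization cloud of a single particle
#'
#' Each template site is independently retained with probability `dol`; each
#' retained site emits a Poisson number of localizations. Every localization
#' is the (deformed, mirrored, posed) site position plus Gaussian noise drawn
#' with its own uncertainty sigma, which is stored alongside. If no
#' localization results, the draw is repeated (counted in attribute
#' `redraws`).
#'
#' @param template a [SiteTemplate-class].
#' @param acq an [AcquisitionModel-class].
#' @param pose a `rigidTransform` (defaults to identity).
#' @param mirror reflect about the x-axis before rotation.
#' @param deformation elliptical axis ratio (1 = none).
#' @param zScale axial scaling for 3D templates.
#' @param id particle identifier.
#' @return A [LocalizationSet-class]. Uses the current RNG state; seed the
#'   generator (or use [makeDataset()]) for reproducibility.
#' @examples
#' set.seed(1)
#' sampleParticle(makeTemplate("grid"), acquisitionModel())
#' @export
sampleParticle <- function(template, acq, pose = NULL, mirror = FALSE,
                           deformation = 1, zScale = 1, id = NA_character_) {
  stopifnot(is(template, "SiteTemplate"), is(acq, "AcquisitionModel"))
  sites <- template@coords
  d <- ncol(sites)
  if (is.null(pose)) pose <- identityTransform(d)
  if (pose$dim != d) stop("pose dimensionality does not match template")

  if (deformation != 1) {
    sites[, 1] <- sites[, 1] * sqrt(deformation)
    sites[, 2] <- sites[, 2] / sqrt(deformation)
  }
  if (d == 3L && zScale != 1) sites[, 3] <- sites[, 3] * zScale

  redraws <- 0L
  repeat {
    keep <- runif(nrow(sites)) < acq@dol
    counts <- if (acq@locsDist == "fixed") {
      rep(as.integer(round(acq@locsPerSite)), sum(keep))
    } else rpois(sum(keep), acq@locsPerSite)
    if (any(keep) && sum(counts) > 0L) break
    redraws <- redraws + 1L
  }
  centers <- sites[keep, , drop = FALSE][rep(seq_len(sum(keep)), counts), ,
                                         drop = FALSE]
  n <- nrow(centers)
  sigma <- rgamma(n, shape = acq@sigmaShape,
                  scale = acq@sigmaMeanNm / acq@sigmaShape)
  sigmaZ <- numeric(0)
  if (d == 2L) {
    # isotropic lateral noise commutes with rigid motions, so it is added in
    # the template frame (before mirroring/pose): a mirrored draw is then the
    # exact reflection of the unmirrored draw under the same RNG state
    centers[, 1] <- centers[, 1] + rnorm(n, 0, sigma)
    centers[, 2] <- centers[, 2] + rnorm(n, 0, sigma)
    if (mirror) centers[, 2] <- -centers[, 2]
    out <- applyTransform(pose, centers)
  } else {
    # anisotropic (lateral vs axial) noise must be added in the image frame
    if (mirror) centers[, 2] <- -centers[, 2]
    out <- applyTransform(pose, centers)
    out[, 1] <- out[, 1] + rnorm(n, 0, sigma)
    out[, 2] <- out[, 2] + rnorm(n, 0, sigma)
    sigmaZ <- rgamma(n, shape = acq@sigmaShape,
                     scale = acq@sigmaZMeanNm / acq@sigmaShape)
    out[, 3] <- out[, 3] + rnorm(n, 0, sigmaZ)
  }
  ls <- LocalizationSet(out, sigma, sigmaZ, id = id)
  attr(ls, "redraws") <- redraws
  ls
}

#' Generate a labelled synthetic particle dataset
#'
#' Draws `nParticles` particles with class labels sampled from the component
#' fractions; each particle gets a uniformly random rotation and a small
#' random translation (within +/- 0.25 of the template extent, mimicking
#' picked particles that are already roughly centered). Fully reproducible
#' from `spec@seed`.
#'
#' @param spec a [MixtureSpec-class].
#' @param acq an [AcquisitionModel-class].
#' @return A [ParticleSet-class] with ground-truth labels in
#'   [trueClasses()].
#' @examples
#' tpl <- makeTemplate("ring")
#' ps <- makeDataset(mixtureSpec(list(list(template = tpl, fraction = 1)),
#'                               5, seed = 7), acquisitionModel())
#' length(ps)
#' @export
makeDataset <- function(spec, acq = acquisitionModel()) {
  stopifnot(is(spec, "MixtureSpec"), is(acq, "AcquisitionModel"))
  d <- ncol(spec@components[[1]]$template@coords)
  for (cm in spec@components)
    if (ncol(cm$template@coords) != d)
      stop("all components must have the same dimensionality")
  withSeed(spec@seed, {
    fr <- vapply(spec@components, `[[`, numeric(1), "fraction")
    labels <- sample.int(length(fr), spec@nParticles, replace = TRUE,
                         prob = fr)
    parts <- vector("list", spec@nParticles)
    poses <- vector("list", spec@nParticles)
    for (i in seq_len(spec@nParticles)) {
      cm <- spec@components[[labels[i]]]
      ext <- max(apply(cm$template@coords, 2,
                       function(v) diff(range(v))))
      shift <- runif(d, -0.25 * ext, 0.25 * ext)
      if (d == 2L) {
        pose <- rigidTransform(theta = runif(1, 0, 2 * pi), t = shift)
      } else {
        pose <- rigidTransform(R = .randomRotation3D(), t = shift)
      }
      parts[[i]] <- sampleParticle(cm$template, acq, pose = pose,
                                   mirror = cm$mirror,
                                   deformation = cm$deformation,
                                   zScale = cm$zScale,
                                   id = sprintf("p%04d", i))
      poses[[i]] <- pose
    }
    new("ParticleSet", particles = parts, trueClass = as.integer(labels),
        templateNames = vapply(spec@components,
                               function(cm) cm$template@name, character(1)),
        poses = poses, seed = spec@seed)
  })
}

#' Standard four-class template mixture
#'
#' The reference multi-class study condition of the package: four templates
#' with 12 binding sites each but distinct arrangements - the 4 x 3 grid
#' (20 nm spacing), a T-shaped dot pattern, a 12-dot ring (90 nm diameter)
#' and an X-shaped dot pattern. Equal site counts make the particle classes
#' differ in shape only: with unequal counts the localization-count
#' normalization of the similarity adds a density axis to the dissimilarity
#' that blurs class boundaries at moderate sampling.
#'
#' @return A list of four [SiteTemplate-class] objects (grid, T, ring, X).
#' @examples
#' vapply(standardMixtureTemplates(), function(t) nrow(coords(t)), 1L)
#' @export
standardMixtureTemplates <- function() {
  list(
    grid = makeTemplate("grid", rows = 3, cols = 4, spacing = 20),
    T12 = makeTemplate("dots", dotCoords = rbind(
      cbind(seq(-2.5, 2.5, 1), 2), cbind(0, seq(-3, 1.5, 0.9))),
      name = "T12"),
    ring12 = makeTemplate("ring", nFold = 12, diameter = 90),
    X12 = makeTemplate("dots", dotCoords = rbind(
      cbind(seq(-1.5, 1.5, 0.6), seq(-1.5, 1.5, 0.6)),
      cbind(seq(-1.5, 1.5, 0.6), seq(1.5, -1.5, -0.6))),
      name = "X12"))
}

# uniform random rotation from normalized quaternion
.randomRotation3D <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}
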