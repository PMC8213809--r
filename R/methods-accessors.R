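# Accessor and show methods.

#' @rdname accessors
#' @export
setMethod("coords", "LocalizationSet", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("coords", "SiteTemplate", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("coords", "MDSEmbedding", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("sigmas", "LocalizationSet", function(x) x@sigma)

#' @rdname accessors
#' @export
setMethod("sigmasAxial", "LocalizationSet", function(x) x@sigmaZ)

#' @rdname accessors
#' @export
setMethod("nLocs", "LocalizationSet", function(x) nrow(x@coords))

#' @rdname accessors
#' @export
setMethod("spatialDims", "LocalizationSet", function(x) ncol(x@coords))

#' @rdname accessors
#' @export
setMethod("particleId", "LocalizationSet", function(x) x@id)

#' @rdname accessors
#' @export
setMethod("particles", "ParticleSet", function(x) x@particles)

#' @rdname accessors
#' @export
setMethod("trueClasses", "ParticleSet", function(x) x@trueClass)

#' @rdname accessors
#' @export
setMethod("length", "ParticleSet", function(x) length(x@particles))

#' @rdname accessors
#' @export
setMethod("similarity", "DissimilarityMatrix", function(x) x@S)

#' @rdname accessors
#' @export
setMethod("dissimilarity", "DissimilarityMatrix", function(x) x@D)

#' @rdname accessors
#' @export
setMethod("stressValue", "MDSEmbedding", function(x) x@stress)

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("nClusters", "ClusterResult", function(x) x@K)

#' @rdname accessors
#' @export
setMethod("silhouetteWidths", "ClusterResult", function(x) x@silhouette)

#' @rdname accessors
#' @export
setMethod("meanSilhouette", "ClusterResult", function(x) x@meanSilhouette)

#' @rdname accessors
#' @export
setMethod("mergeMap", "EigenImageSet", function(x) x@mergeMap)

#' @rdname accessors
#' @export
setMethod("eigenWeights", "EigenImageSet", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("singularValues", "EigenImageSet", function(x) x@singularValues)

#' @rdname accessors
#' @export
setMethod("ellipticity", "EllipseFit", function(x) x@e)

# -- subsetting ---------------------------------------------------------------

#' @rdname accessors
#' @param ... unused.
#' @param drop unused.
#' @export
setMethod("[", "ParticleSet", function(x, i, j, ..., drop = TRUE) {
  new("ParticleSet", particles = x@particles[i],
      trueClass = if (length(x@trueClass)) x@trueClass[i] else integer(0),
      templateNames = x@templateNames,
      poses = if (length(x@poses)) x@poses[i] else list(), seed = x@seed)
})

# -- show ---------------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("show", "LocalizationSet", function(object) {
  cat(sprintf("LocalizationSet '%s': %d localizations (%dD), mean sigma %.2f nm\n",
              object@id, nrow(object@coords), ncol(object@coords),
              mean(object@sigma)))
})

#' @rdname accessors
#' @export
setMethod("show", "ParticleSet", function(object) {
  n <- length(object@particles)
  d <- if (n) ncol(object@particles[[1]]@coords) else NA_integer_
  cat(sprintf("ParticleSet: %d particles (%sD)\n", n, d))
  if (length(object@trueClass)) {
    tb <- table(object@trueClass)
    cat("  true classes:",
        paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
})

#' @rdname accessors
#' @export
setMethod("show", "DissimilarityMatrix", function(object) {
  N <- nrow(object@D)
  cat(sprintf("DissimilarityMatrix: %d particles (%dD), scale %.4g px (%.2f nm)\n",
              N, object@dims, object@scale, object@scale * object@pixelNm))
  if (N > 1) {
    off <- object@D[upper.tri(object@D)]
    cat(sprintf("  D range [0, %.4g], %d/%d pairs with all starts converged\n",
                max(off), sum(object@nStartsConverged > 0L),
                length(object@nStartsConverged)))
  }
})

#' @rdname accessors
#' @export
setMethod("show", "MDSEmbedding", function(object) {
  cat(sprintf("MDSEmbedding: %d particles in %d dims, stress %.4g (%s, %d iterations)\n",
              nrow(object@coords), ncol(object@coords), object@stress,
              if (object@converged) "converged" else "not converged",
              length(object@trace)))
})

#' @rdname accessors
#' @export
setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: K = %d, total within-SS %.4g, mean silhouette %s\n",
              object@K, object@totWithinSS,
              ifelse(is.na(object@meanSilhouette), "NA",
                     sprintf("%.3f", object@meanSilhouette))))
  tb <- table(object@labels)
  cat("  sizes:", paste(as.integer(tb), collapse = ", "), "\n")
})

#' @rdname accessors
#' @export
setMethod("show", "FusedReconstruction", function(object) {
  cat(sprintf("FusedReconstruction: %d members, %d pooled localizations (reference '%s')\n",
              length(object@memberIds), nrow(object@locs@coords),
              object@reference))
})

#' @rdname accessors
#' @export
setMethod("show", "EigenImageSet", function(object) {
  K <- dim(object@images)[3]
  cat(sprintf("EigenImageSet: %d images of %d x %d px\n", K, object@nPix,
              object@nPix))
  cat("  singular values:", paste(sprintf("%.3g", head(object@singularValues, 5)),
                                  collapse = ", "),
      if (K > 5) "...\n" else "\n")
  if (length(object@mergeMap))
    cat("  merge map:", paste(object@mergeMap, collapse = " "), "\n")
})

#' @rdname accessors
#' @export
setMethod("show", "EllipseFit", function(object) {
  cat(sprintf("EllipseFit: a = %.2f nm, b = %.2f nm, e = %.3f, theta = %.1f deg\n",
              object@a, object@b, object@e, object@theta * 180 / pi))
})
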