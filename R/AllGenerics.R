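# Generics and accessors.

#' @name accessors
#' @title Accessors for pipeline objects
#' @description Slot accessors for the S4 containers of the package.
#' @param x an object.
#' @param object an object (for `show`).
#' @param i,j particle indices (for [pairTransform()]).
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("sigmas", function(x) standardGeneric("sigmas"))

#' @rdname accessors
#' @export
setGeneric("sigmasAxial", function(x) standardGeneric("sigmasAxial"))

#' @rdname accessors
#' @export
setGeneric("nLocs", function(x) standardGeneric("nLocs"))

#' @rdname accessors
#' @export
setGeneric("spatialDims", function(x) standardGeneric("spatialDims"))

#' @rdname accessors
#' @export
setGeneric("particleId", function(x) standardGeneric("particleId"))

#' @rdname accessors
#' @export
setGeneric("particles", function(x) standardGeneric("particles"))

#' @rdname accessors
#' @export
setGeneric("trueClasses", function(x) standardGeneric("trueClasses"))

#' @rdname accessors
#' @export
setGeneric("similarity", function(x) standardGeneric("similarity"))

#' @rdname accessors
#' @export
setGeneric("dissimilarity", function(x) standardGeneric("dissimilarity"))

#' Optimal rigid transform of a registered pair
#'
#' Returns the rigid transform found by the all-to-all registration that maps
#' particle `j` into the frame of particle `i` (the inverse of the stored
#' transform if `i > j`).
#'
#' @param x a [DissimilarityMatrix-class].
#' @param i,j particle indices.
#' @return A `rigidTransform` (list with rotation matrix `R`, translation
#'   `t` and `dim`).
#' @export
setGeneric("pairTransform", function(x, i, j) standardGeneric("pairTransform"))

#' @rdname accessors
#' @export
setGeneric("stressValue", function(x) standardGeneric("stressValue"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname accessors
#' @export
setGeneric("silhouetteWidths", function(x) standardGeneric("silhouetteWidths"))

#' @rdname accessors
#' @export
setGeneric("meanSilhouette", function(x) standardGeneric("meanSilhouette"))

#' @rdname accessors
#' @export
setGeneric("mergeMap", function(x) standardGeneric("mergeMap"))

#' @rdname accessors
#' @export
setGeneric("eigenWeights", function(x) standardGeneric("eigenWeights"))

#' @rdname accessors
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))

#' @rdname accessors
#' @export
setGeneric("ellipticity", function(x) standardGeneric("ellipticity"))
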