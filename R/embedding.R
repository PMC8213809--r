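# Metric MDS embedding of the dissimilarity matrix, multi-restart k-means,
# and silhouette-guided selection of the cluster count K.

#' Normalized metric stress
#'
#' `sqrt( sum_{i<j} (d_ij - |x_i - x_j|)^2 / sum_{i<j} d_ij^2 )`: the root of
#' the squared mismatch between the embedding distances and the target
#' dissimilarities, normalized by the total squared dissimilarity.
#'
#' @param D dissimilarity matrix (or [DissimilarityMatrix-class]).
#' @param X embedding coordinates, one row per particle.
#' @return The stress value (0 for a perfect embedding).
#' @examples
#' X <- cbind(c(0, 3, 0), c(0, 0, 4))
#' mdsStress(as.matrix(dist(X)), X)  # 0
#' @export
mdsStress <- function(D, X) {
  D <- .asDissMatrix(D)
  X <- as.matrix(X)
  if (nrow(D) != nrow(X)) stop("D and X sizes differ")
  up <- upper.tri(D)
  den <- sum(D[up]^2)
  if (den == 0) stop("all dissimilarities are zero; stress is undefined")
  dx <- as.matrix(dist(X))
  sqrt(sum((D[up] - dx[up])^2) / den)
}

.asDissMatrix <- function(D) {
  if (is(D, "DissimilarityMatrix")) D <- D@D
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("D must be square")
  if (max(abs(D - t(D))) > 1e-8) stop("D must be symmetric")
  if (any(D < 0)) stop("D must be non-negative")
  D
}

#' Metric MDS by stress majorization
#'
#' Embeds the dissimilarity matrix into `d` dimensions by iterative stress
#' minimization (SMACOF majorization, which guarantees a non-increasing
#' stress sequence), initialized from the classical (eigendecomposition)
#' solution. Iterations stop when the relative stress change falls below
#' `tol`.
#'
#' @param D dissimilarity matrix or [DissimilarityMatrix-class].
#' @param d embedding dimensionality (default 30; capped at N-1 with a
#'   warning).
#' @param tol relative stress-change tolerance.
#' @param maxIter maximum majorization iterations.
#' @param seed seed for the tiny jitter used when the classical solution
#'   spans fewer than `d` dimensions.
#' @return An [MDSEmbedding-class].
#' @export
mdsEmbed <- function(D, d = 30L, tol = 1e-6, maxIter = 300L, seed = NULL) {
  D <- .asDissMatrix(D)
  N <- nrow(D)
  if (d < 1L) stop("d must be >= 1")
  if (d > N - 1L) {
    warning(sprintf("embedding dimensions capped at N-1 = %d", N - 1L))
    d <- N - 1L
  }
  up <- upper.tri(D)
  den <- sum(D[up]^2)
  if (den == 0) stop("all dissimilarities are zero")

  X <- suppressWarnings(cmdscale(D, k = d))
  if (ncol(X) < d) {
    pad <- withSeed(seed, matrix(rnorm(N * (d - ncol(X)), 0,
                                       1e-8 * max(D) + 1e-300), N))
    X <- cbind(X, pad)
  }
  stress <- function(X) {
    dx <- as.matrix(dist(X))
    sqrt(sum((D[up] - dx[up])^2) / den)
  }
  trace <- stress(X)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    dx <- as.matrix(dist(X))
    B <- -D / (dx + (dx == 0))
    B[dx == 0] <- 0
    diag(B) <- -rowSums(B) + diag(B)
    X <- (B %*% X) / N
    s <- stress(X)
    trace <- c(trace, s)
    prev <- trace[length(trace) - 1L]
    if (prev - s < tol * prev) { converged <- TRUE; break }
  }
  dimnames(X) <- list(rownames(D), NULL)
  new("MDSEmbedding", coords = X, stress = trace[length(trace)],
      trace = trace, converged = converged)
}

#' Multi-restart k-means clustering
#'
#' Runs Lloyd's k-means from `nRestarts` random point-seedings and keeps the
#' solution with the lowest total within-cluster sum of squared
#' point-to-centroid distances (ties broken by the first restart that
#' achieved it). For hunting rare classes, set `nRestarts` to at least the
#' number of particles so every particle is, on average, selected as an
#' initial seed at least once.
#'
#' @param X embedding coordinates (or an [MDSEmbedding-class]).
#' @param K number of clusters (1..N).
#' @param nRestarts number of random restarts.
#' @param seed seed controlling the restarts (labels are deterministic given
#'   it).
#' @param silhouetteDims leading dimensions the silhouette is evaluated on
#'   (0 disables silhouette computation).
#' @return A [ClusterResult-class].
#' @export
kmeansCluster <- function(X, K, nRestarts = 1000L, seed = NULL,
                          silhouetteDims = 3L) {
  if (is(X, "MDSEmbedding")) X <- X@coords
  X <- as.matrix(X)
  N <- nrow(X)
  K <- as.integer(K)
  if (K < 1L || K > N) stop("K must be in 1..N")
  withSeed(seed, {
    best <- NULL
    nFail <- 0L
    if (K == N) {
      best <- list(cluster = seq_len(N), tot.withinss = 0)
    } else {
      for (r in seq_len(nRestarts)) {
        centers <- X[sample.int(N, K), , drop = FALSE]
        km <- tryCatch(
          suppressWarnings(kmeans(X, centers = centers, iter.max = 100L,
                                  algorithm = "Lloyd")),
          error = function(e) NULL)
        if (is.null(km) || length(unique(km$cluster)) != K) {
          nFail <- nFail + 1L
          next
        }
        if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
      }
      if (is.null(best))
        stop("all k-means restarts failed; K may be too large for the data")
    }
    labels <- as.integer(best$cluster)
    sil <- rep(NA_real_, N)
    msil <- NA_real_
    sdim <- 0L
    if (silhouetteDims > 0L && K >= 2L) {
      sdim <- min(as.integer(silhouetteDims), ncol(X))
      sv <- silhouetteValues(X[, seq_len(sdim), drop = FALSE], labels)
      sil <- sv$values
      msil <- sv$mean
    }
    new("ClusterResult", labels = labels, K = K,
        totWithinSS = as.numeric(best$tot.withinss), silhouette = sil,
        meanSilhouette = msil, silhouetteDims = sdim,
        nRestarts = as.integer(nRestarts), nFailedRestarts = nFail)
  })
}

#' Silhouette values
#'
#' Per-point silhouette `(b_i - a_i) / max(a_i, b_i)`, where `a_i` is the
#' mean distance of point i to the other members of its cluster and `b_i`
#' the minimum over other clusters of the mean distance to that cluster's
#' members. Following common convention, points in singleton clusters get
#' value 0. Distances are Euclidean on the supplied coordinates; pass the
#' first three embedding dimensions to reproduce the pipeline's K-selection
#' diagnostic.
#'
#' @param X coordinates (typically the first 3 MDS dimensions).
#' @param labels integer cluster labels.
#' @return A list with `values` (per point) and `mean`.
#' @export
silhouetteValues <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  N <- nrow(X)
  if (length(labels) != N) stop("labels length must match rows of X")
  cl <- sort(unique(labels))
  if (length(cl) < 2L) stop("silhouette requires at least 2 clusters")
  dx <- as.matrix(dist(X))
  vals <- numeric(N)
  sizes <- table(factor(labels, levels = cl))
  for (i in seq_len(N)) {
    own <- labels[i]
    if (sizes[[as.character(own)]] == 1L) { vals[i] <- 0; next }
    a <- mean(dx[i, labels == own & seq_len(N) != i])
    b <- min(vapply(cl[cl != own],
                    function(g) mean(dx[i, labels == g]), numeric(1)))
    vals[i] <- (b - a) / max(a, b)
  }
  list(values = vals, mean = mean(vals))
}

#' Silhouette-guided suggestion for the number of clusters K
#'
#' Clusters a shared embedding at every K in `kRange` and reports the mean
#' silhouette (computed on the first three embedding dimensions). The argmax
#' is a suggestion only: inspect the table and the embedding scatter before
#' committing, and prefer a deliberately high K when hunting rare classes.
#'
#' @param D dissimilarity matrix or [DissimilarityMatrix-class], or an
#'   [MDSEmbedding-class] to reuse.
#' @param kRange candidate cluster counts.
#' @param d embedding dimensionality (if `D` needs embedding).
#' @param nRestarts k-means restarts per K.
#' @param seed seed shared by the embedding jitter and all k-means runs.
#' @return A list: `table` (data.frame of K and mean silhouette),
#'   `suggested` (argmax K), `embedding`.
#' @export
suggestK <- function(D, kRange = 2:10, d = 30L, nRestarts = 1000L,
                     seed = NULL) {
  if (!length(kRange)) stop("kRange is empty")
  emb <- if (is(D, "MDSEmbedding")) D else mdsEmbed(D, d = d, seed = seed)
  N <- nrow(emb@coords)
  kRange <- kRange[kRange >= 2L & kRange <= N - 1L]
  if (!length(kRange)) stop("no valid K in kRange (need 2..N-1)")
  ms <- vapply(kRange, function(K) {
    kmeansCluster(emb, K, nRestarts = nRestarts, seed = seed)@meanSilhouette
  }, numeric(1))
  tab <- data.frame(K = as.integer(kRange), meanSilhouette = ms)
  list(table = tab, suggested = tab$K[which.max(ms)], embedding = emb)
}
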