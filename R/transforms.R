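# Rigid transforms: r' = R %*% r + t, with det(R) = +1 (reflections are never
# part of the search space; mirrored structures must separate through their
# dissimilarity instead).

#' Construct a rigid transform
#'
#' @param theta 2D rotation angle in radians (ignored if `R` given).
#' @param t translation vector (length 2 or 3, nm).
#' @param R rotation matrix (2x2 or 3x3, proper: det = +1).
#' @return A list with elements `R`, `t` and `dim`, class `rigidTransform`.
#' @examples
#' tr <- rigidTransform(theta = pi / 2, t = c(10, 0))
#' applyTransform(tr, cbind(1, 0))
#' @export
rigidTransform <- function(theta = 0, t = c(0, 0), R = NULL) {
  if (is.null(R)) {
    R <- rotationMatrix2D(theta)
  } else {
    R <- as.matrix(R)
    if (abs(det(R) - 1) > 1e-6)
      stop("rotation must be proper (det = +1); reflections are not allowed")
  }
  if (nrow(R) != length(t)) stop("rotation and translation dimensions differ")
  structure(list(R = R, t = as.numeric(t), dim = nrow(R)),
            class = "rigidTransform")
}

#' @rdname rigidTransform
#' @export
rotationMatrix2D <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' @rdname rigidTransform
#' @param x a `rigidTransform`.
#' @export
invertTransform <- function(x) {
  Rt <- t(x$R)
  rigidTransform(t = as.numeric(-Rt %*% x$t), R = Rt)
}

#' @rdname rigidTransform
#' @param coords numeric matrix of positions (rows).
#' @export
applyTransform <- function(x, coords) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(x$R), 2, -x$t)
}

#' @rdname rigidTransform
#' @export
identityTransform <- function(dim = 2) {
  rigidTransform(t = rep(0, dim), R = diag(dim))
}

#' @rdname rigidTransform
#' @param e1,e2 two `rigidTransform`s; returns the composition applying `e2`
#'   first, then `e1`.
#' @export
composeTransforms <- function(e1, e2) {
  rigidTransform(t = as.numeric(e1$R %*% e2$t + e1$t), R = e1$R %*% e2$R)
}

#' @rdname rigidTransform
#' @param dim spatial dimensionality.
#' @export
print.rigidTransform <- function(x, ...) {
  if (x$dim == 2) {
    cat(sprintf("rigidTransform 2D: theta = %.3f rad, t = (%.2f, %.2f) nm\n",
                atan2(x$R[2, 1], x$R[1, 1]), x$t[1], x$t[2]))
  } else {
    cat("rigidTransform 3D: t =", sprintf("%.2f", x$t), "nm, R =\n")
    print(round(x$R, 4))
  }
  invisible(x)
}

# rotation taking the z-axis onto each vertex of a regular icosahedron,
# composed with nInPlane in-plane rotations: initializations of the 3D pose
# search (the 3D analogue of the uniformly spaced 2D start angles).
icosahedronRotations <- function(nInPlane = 4L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  v <- v / sqrt(rowSums(v^2))
  rots <- list()
  for (k in seq_len(nrow(v))) {
    # minimal rotation taking e_z to v[k, ]
    z <- c(0, 0, 1)
    axis <- c(z[2] * v[k, 3] - z[3] * v[k, 2],
              z[3] * v[k, 1] - z[1] * v[k, 3],
              z[1] * v[k, 2] - z[2] * v[k, 1])
    s <- sqrt(sum(axis^2))
    cth <- sum(z * v[k, ])
    if (s < 1e-12) {
      Rv <- if (cth > 0) diag(3) else diag(c(1, -1, -1))
    } else {
      axis <- axis / s
      th <- atan2(s, cth)
      Kx <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                     axis[2], -axis[1], 0), 3, 3)
      Rv <- diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
    }
    for (a in seq_len(nInPlane)) {
      ang <- 2 * pi * (a - 1) / nInPlane
      Rz <- diag(3)
      Rz[1:2, 1:2] <- rotationMatrix2D(ang)
      rots[[length(rots) + 1L]] <- Rv %*% Rz
    }
  }
  rots
}

# evaluate expressions under a temporary seed, restoring the RNG state
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 1-based linear index of the unordered pair (i < j) in row-major order
pairIndex <- function(i, j, N) {
  if (i == j) stop("no transform is stored for a particle with itself")
  if (i > j) { k <- i; i <- j; j <- k }
  (i - 1) * N - i * (i - 1) / 2 + (j - i)
}
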