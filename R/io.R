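# Localization table I/O and run manifests.
#
# Native CSV schema (one row per localization):
#   particle_id, x_nm, y_nm[, z_nm], sigma_nm[, sigma_z_nm][, true_class]
# Picasso-style CSV tables (x, y in camera pixels with lpx/lpy uncertainties
# and a `group` particle id) are converted to nm on load. HDF5 localization
# tables are not supported by this build; export them to CSV first.

#' Write particles to a localization CSV
#'
#' @param particles [ParticleSet-class] or list of [LocalizationSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeLocalizations <- function(particles, path) {
  trueClass <- if (is(particles, "ParticleSet") &&
                   length(particles@trueClass)) particles@trueClass else NULL
  plist <- .asParticleList(particles)
  d <- ncol(plist[[1]]@coords)
  rows <- lapply(seq_along(plist), function(i) {
    p <- plist[[i]]
    df <- data.frame(particle_id = rep(p@id, nLocs(p)),
                     x_nm = p@coords[, 1], y_nm = p@coords[, 2])
    if (d == 3L) df$z_nm <- p@coords[, 3]
    df$sigma_nm <- p@sigma
    if (length(p@sigmaZ)) df$sigma_z_nm <- p@sigmaZ
    if (!is.null(trueClass)) df$true_class <- trueClass[i]
    df
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read particles from a localization table
#'
#' @param path input file.
#' @param format `"csv"` (native schema above) or `"picasso-csv"` (columns
#'   `group`, `x`, `y`, `lpx`, `lpy` in camera pixels, converted to nm with
#'   `pixelNm`). Picasso HDF5 is not supported; convert to CSV first.
#' @param pixelNm camera pixel size used for pixel-unit input.
#' @return A [ParticleSet-class]; particles with fewer than 3 localizations
#'   are flagged with a warning (their pose cannot be optimized).
#' @export
readLocalizations <- function(path, format = c("csv", "picasso-csv",
                                               "picasso-hdf5"),
                              pixelNm = 130) {
  format <- match.arg(format)
  if (format == "picasso-hdf5")
    stop("HDF5 localization tables are not supported by this build; ",
         "export the table to CSV (columns group, x, y, lpx, lpy) and use ",
         "format = 'picasso-csv'")
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty localization table: ", path)

  if (format == "picasso-csv") {
    need <- c("group", "x", "y", "lpx", "lpy")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
    df <- data.frame(particle_id = df$group,
                     x_nm = df$x * pixelNm, y_nm = df$y * pixelNm,
                     sigma_nm = (df$lpx + df$lpy) / 2 * pixelNm)
  } else {
    need <- c("particle_id", "x_nm", "y_nm", "sigma_nm")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  }
  if (any(df$sigma_nm <= 0)) stop("non-positive sigma in input")
  has3d <- "z_nm" %in% names(df)
  ids <- unique(df$particle_id)
  parts <- lapply(ids, function(id) {
    sub <- df[df$particle_id == id, , drop = FALSE]
    coords <- if (has3d) cbind(sub$x_nm, sub$y_nm, sub$z_nm) else
      cbind(sub$x_nm, sub$y_nm)
    sz <- if ("sigma_z_nm" %in% names(sub)) sub$sigma_z_nm else numeric(0)
    LocalizationSet(coords, sub$sigma_nm, sz, id = as.character(id))
  })
  small <- sum(vapply(parts, nLocs, integer(1)) < 3L)
  if (small > 0L)
    warning(sprintf("%d particle(s) with < 3 localizations (pose cannot be optimized)",
                    small))
  trueClass <- if ("true_class" %in% names(df)) {
    as.integer(df$true_class[match(ids, df$particle_id)])
  } else integer(0)
  new("ParticleSet", particles = parts, trueClass = trueClass,
      templateNames = character(0), seed = NA_integer_)
}

#' Write / read a run manifest
#'
#' The manifest records everything needed to reproduce a run: the
#' configuration, all seeds, and package/R versions, as structured YAML.
#'
#' @param manifest a named list.
#' @param path file path.
#' @return `path` (write) or the manifest list (read).
#' @export
writeManifest <- function(manifest, path) {
  manifest$versions <- list(
    package = as.character(packageVersion("smlmClassify")),
    R = paste(R.version$major, R.version$minor, sep = "."))
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) yaml::read_yaml(path)
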