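#' Construct a landmark configuration
#'
#' A configuration is a fixed-length ordered set of 2-D (semi)landmarks for
#' one specimen.
#'
#' @param points Numeric matrix with two columns (x, y), k >= 3 rows.
#' @param specimen_id Optional specimen identifier.
#' @return Object of class `"configuration"`: list with `points` and
#'   `specimen_id`.
#' @export
configuration <- function(points, specimen_id = NA_character_) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("configuration points must have two columns")
  if (nrow(points) < 3L) stop("a configuration needs at least 3 landmarks")
  storage.mode(points) <- "double"
  if (anyNA(points)) stop("configuration contains NA coordinates")
  if (all(points[, 1L] == points[1L, 1L]) &&
      all(points[, 2L] == points[1L, 2L])) {
    stop("all landmarks coincident")
  }
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(points = points, specimen_id = as.character(specimen_id)),
            class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("<configuration '%s': %d landmarks, centroid size %.6g>\n",
              x$specimen_id, nrow(x$points), centroid_size(x)))
  invisible(x)
}

#' Centroid size of a configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid -- the standard geometric-morphometric size measure
#' removed by Procrustes superimposition.
#'
#' @param config A [configuration()] or a k x 2 matrix.
#' @return Positive numeric scalar.
#' @export
centroid_size <- function(config) {
  p <- if (inherits(config, "configuration")) config$points else as.matrix(config)
  cs <- sqrt(sum(sweep(p, 2L, colMeans(p))^2))
  if (cs == 0) stop("centroid size is zero: all landmarks coincident")
  cs
}

# Center at the origin and scale to unit centroid size (preshape).
preshape <- function(config) {
  p <- if (inherits(config, "configuration")) config$points else as.matrix(config)
  p <- sweep(p, 2L, colMeans(p))
  p / sqrt(sum(p^2))
}

config_vec <- function(points) as.numeric(points)  # column-major (all x, all y)

vec_config <- function(v) matrix(v, ncol = 2L)
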