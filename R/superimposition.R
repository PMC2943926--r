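#' Optimal rotation and partial Procrustes distance between two shapes
#'
#' Both configurations are centered and scaled to unit centroid size
#' internally; the rotation minimizing the summed squared landmark
#' differences is found from the singular-value decomposition of the
#' cross-product matrix. Reflections (determinant -1) are excluded unless
#' `allow_reflection = TRUE` -- dorsal-view pronota have a fixed handedness,
#' but mirrored fossil figures can be accommodated.
#'
#' @param moving,target [configuration()]s (or k x 2 matrices) with equal
#'   landmark counts.
#' @param allow_reflection Permit an orientation-reversing map?
#' @return List with `rotation` (2 x 2 orthogonal matrix applied to the
#'   moving preshape on the right), `distance` (the partial Procrustes
#'   distance, the square root of the minimized sum of squared differences)
#'   and `aligned` (the moving preshape after rotation).
#' @export
align_pair <- function(moving, target, allow_reflection = FALSE) {
  X <- preshape(moving)
  Y <- preshape(target)
  if (nrow(X) != nrow(Y)) stop("landmark counts differ")
  A <- crossprod(X, Y)            # 2x2
  sv <- svd(A)
  s <- c(1, 1)
  if (!allow_reflection && det(sv$u %*% t(sv$v)) < 0) s[2L] <- -1
  R <- sv$u %*% diag(s) %*% t(sv$v)
  XR <- X %*% R
  d2 <- sum((Y - XR)^2)
  list(rotation = R, distance = sqrt(max(d2, 0)), aligned = XR)
}

#' Partial Procrustes distance between two configurations
#'
#' Convenience wrapper around [align_pair()].
#' @inheritParams align_pair
#' @return Non-negative numeric scalar.
#' @export
procrustes_distance <- function(moving, target, allow_reflection = FALSE) {
  align_pair(moving, target, allow_reflection)$distance
}

#' Geodesic (Procrustes) distance from a partial Procrustes distance
#'
#' Great-circle distance in radians between preshapes on the unit sphere:
#' rho = 2 * asin(d / 2).
#'
#' @param partial_d Partial Procrustes distance(s) in `[0, 2]`.
#' @return Geodesic distance(s) in radians.
#' @export
geodesic_distance <- function(partial_d) {
  if (any(partial_d < 0 | partial_d > 2)) {
    stop("partial Procrustes distance must lie in [0, 2]")
  }
  2 * asin(partial_d / 2)
}

#' Generalized least-squares Procrustes superimposition
#'
#' Iterative GPA in the tps-suite's GLS convention: every configuration is
#' centered and scaled to unit centroid size (partial Procrustes -- full
#' renormalization each iteration, not optimal-beta rescaling), the first
#' configuration seeds the consensus, and the algorithm alternates rotating
#' all configurations to the consensus with recomputing the consensus as
#' the renormalized arithmetic mean, until the consensus moves less than
#' `tol` (partial Procrustes distance between successive consensuses) or
#' `max_iter` is reached. A final rotation pass leaves every configuration
#' optimally rotated to the returned consensus.
#'
#' @param configs List of [configuration()]s with equal landmark counts.
#' @param tol Convergence tolerance on consensus movement.
#' @param max_iter Maximum number of iterations.
#' @param allow_reflection Permit reflections when rotating to consensus?
#' @return Object of class `"aligned_set"`: list with `aligned` (list of
#'   configurations, centered, unit centroid size, rotated to consensus),
#'   `consensus` (unit-size GLS reference), `centroid_sizes`
#'   (pre-normalization sizes), `iterations` and `converged`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L,
                allow_reflection = FALSE) {
  if (length(configs) == 0L) stop("gpa needs at least one configuration")
  ids <- vapply(configs, function(cc)
    if (inherits(cc, "configuration")) cc$specimen_id else NA_character_, "")
  sizes <- vapply(configs, centroid_size, 0)
  X <- lapply(configs, preshape)
  k <- nrow(X[[1L]])
  if (!all(vapply(X, nrow, 0L) == k)) stop("landmark counts differ")
  consensus <- X[[1L]]
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    X <- lapply(X, function(x) align_pair(x, consensus,
                                          allow_reflection)$aligned)
    new_cons <- Reduce(`+`, X) / length(X)
    new_cons <- sweep(new_cons, 2L, colMeans(new_cons))
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    moved <- align_pair(new_cons, consensus, allow_reflection)$distance
    consensus <- new_cons
    if (moved < tol) { converged <- TRUE; break }
  }
  X <- lapply(X, function(x) align_pair(x, consensus, allow_reflection)$aligned)
  aligned <- Map(function(x, id) configuration(x, specimen_id = id), X, ids)
  structure(list(aligned = aligned,
                 consensus = configuration(consensus, specimen_id = "consensus"),
                 centroid_sizes = sizes, iterations = iter,
                 converged = converged),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("<aligned_set: %d configurations, %d landmarks, %d iterations%s>\n",
              length(x$aligned), nrow(x$consensus$points), x$iterations,
              if (x$converged) ", converged" else " (not converged)"))
  invisible(x)
}

#' Project aligned configurations into the tangent space at the consensus
#'
#' Each aligned configuration, viewed as a unit vector on the preshape
#' sphere, is orthogonally projected onto the plane tangent to the sphere
#' at the consensus: `x_t = x - z (z . x)` with `z` the consensus unit
#' vector. The consensus itself projects to the zero vector.
#'
#' @param aligned_set Result of [gpa()].
#' @return List of tangent-coordinate matrices (k x 2), one per specimen.
#' @export
tangent_project <- function(aligned_set) {
  stopifnot(inherits(aligned_set, "aligned_set"))
  z <- config_vec(aligned_set$consensus$points)
  z <- z / sqrt(sum(z^2))
  lapply(aligned_set$aligned, function(cfg) {
    x <- config_vec(cfg$points)
    vec_config(x - z * sum(z * x))
  })
}

#' Tangent-space approximation diagnostic
#'
#' For each specimen, the geodesic distance rho (radians) to the consensus
#' and the Euclidean norm Y of its tangent-space projection are computed;
#' the diagnostic regresses Y on rho through the origin and reports the
#' uncentred correlation. When shape variation is small, points in the
#' tangent plane approximate their distribution in shape space and the
#' correlation is very close to 1 (the tps-SMALL test).
#'
#' @param aligned_set Result of [gpa()] with at least 3 specimens.
#' @return Object of class `"tangent_test"`: list with `geodesic_distances`,
#'   `tangent_distances`, `uncentred_correlation`, `slope_through_origin`
#'   and, for reference, the free-intercept regression slope
#'   (`slope_free`). The through-origin fit is the primary diagnostic.
#' @export
tangent_space_test <- function(aligned_set) {
  stopifnot(inherits(aligned_set, "aligned_set"))
  if (length(aligned_set$aligned) < 3L) {
    stop("tangent-space test needs at least 3 specimens")
  }
  cons <- aligned_set$consensus
  rho <- vapply(aligned_set$aligned, function(cfg)
    geodesic_distance(align_pair(cfg, cons)$distance), 0)
  tang <- tangent_project(aligned_set)
  Y <- vapply(tang, function(t) sqrt(sum(t^2)), 0)
  if (!any(rho > 1e-12)) {
    stop("all specimens identical: diagnostic undefined")
  }
  r <- sum(rho * Y) / sqrt(sum(rho^2) * sum(Y^2))
  slope <- sum(rho * Y) / sum(rho^2)
  fit <- stats::lm(Y ~ rho)
  structure(list(geodesic_distances = rho, tangent_distances = Y,
                 uncentred_correlation = r, slope_through_origin = slope,
                 slope_free = unname(stats::coef(fit)[2L])),
            class = "tangent_test")
}

#' @export
print.tangent_test <- function(x, ...) {
  cat(sprintf(paste0("<tangent_test: n = %d, uncentred correlation %.6f, ",
                     "through-origin slope %.6f>\n"),
              length(x$geodesic_distances), x$uncentred_correlation,
              x$slope_through_origin))
  invisible(x)
}
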