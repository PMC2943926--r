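tps_kernel <- function(r2) {
  # U(r) = r^2 log r^2, with U(0) = 0
  u <- numeric(length(r2))
  pos <- r2 > 0
  u[pos] <- r2[pos] * log(r2[pos])
  u
}

tps_L <- function(ref) {
  k <- nrow(ref)
  d2 <- as.matrix(stats::dist(ref))^2
  K <- matrix(tps_kernel(d2), k, k)
  Q <- cbind(1, ref)
  rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3L, 3L)))
}

#' Thin-plate-spline bending energy of a reference configuration
#'
#' Builds the kernel matrix `K` with `U(r) = r^2 log r^2` (`U(0) = 0`), the
#' bordered system `L = [[K, Q], [Q', 0]]` with `Q = [1 | x | y]`, and takes
#' the bending-energy matrix as the upper-left k x k block of `L^-1`. Its
#' eigenvectors are the principal warps; affine (uniform) deformations span
#' its three-dimensional null space, so the matrix is positive-semidefinite
#' with exactly three zero eigenvalues.
#'
#' @param reference A [configuration()] (or k x 2 matrix) with no two
#'   landmarks coincident.
#' @return Object of class `"bending_energy"`: list with `reference`,
#'   `energy_matrix` (k x k, symmetric PSD), `principal_warps`
#'   (eigenvectors, columns, sorted by decreasing eigenvalue) and
#'   `eigenvalues` (non-negative, decreasing).
#' @export
bending_energy <- function(reference) {
  ref <- if (inherits(reference, "configuration")) reference$points else
    as.matrix(reference)
  k <- nrow(ref)
  if (k < 4L) stop("bending energy needs at least 4 landmarks")
  if (any(as.matrix(stats::dist(ref))[upper.tri(diag(k))] == 0)) {
    stop("coincident landmarks: kernel matrix singular")
  }
  L <- tps_L(ref)
  Linv <- solve(L)
  E <- Linv[seq_len(k), seq_len(k), drop = FALSE]
  E <- (E + t(E)) / 2
  eig <- eigen(E, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  structure(list(reference = ref, energy_matrix = E,
                 principal_warps = eig$vectors, eigenvalues = vals),
            class = "bending_energy")
}

#' Thin-plate-spline interpolating warp
#'
#' Fits the pair of thin-plate splines (one per coordinate) mapping each
#' source landmark exactly to its target landmark -- the smoothest
#' interpolating deformation -- and evaluates the fitted map at arbitrary
#' query points, e.g. the nodes of a deformation grid.
#'
#' @param source,target [configuration()]s (or k x 2 matrices) with equal
#'   landmark counts; source landmarks must be distinct.
#' @param points Matrix (m x 2) of query points to map through the warp.
#' @return m x 2 matrix of warped query points.
#' @export
tps_warp <- function(source, target, points) {
  src <- if (inherits(source, "configuration")) source$points else
    as.matrix(source)
  tgt <- if (inherits(target, "configuration")) target$points else
    as.matrix(target)
  if (nrow(src) != nrow(tgt)) stop("landmark counts differ")
  k <- nrow(src)
  if (any(as.matrix(stats::dist(src))[upper.tri(diag(k))] == 0)) {
    stop("coincident source landmarks")
  }
  pts <- as.matrix(points)
  L <- tps_L(src)
  rhs <- rbind(tgt, matrix(0, 3L, 2L))
  coefs <- solve(L, rhs)           # (k+3) x 2: [W; a0; ax; ay]
  W <- coefs[seq_len(k), , drop = FALSE]
  A <- coefs[k + 1:3, , drop = FALSE]
  d2 <- outer(pts[, 1L], src[, 1L], `-`)^2 +
        outer(pts[, 2L], src[, 2L], `-`)^2
  U <- matrix(tps_kernel(d2), nrow(pts), k)
  out <- cbind(1, pts) %*% A + U %*% W
  dimnames(out) <- list(NULL, c("x", "y"))
  out
}

#' Deformation grid of a thin-plate-spline warp
#'
#' Renders the consensus-to-target deformation as a warped regular grid
#' over the source configuration's bounding box (Cartesian-transformation
#' styling), at a chosen magnification of the shape difference.
#'
#' @inheritParams tps_warp
#' @param n_grid Grid lines per side.
#' @param magnify Magnification of the deformation (1 = as observed).
#' @param pad Fractional padding of the bounding box.
#' @return Data frame with columns `x`, `y` (warped node positions),
#'   `row`, `col` (grid indices), suitable for line plotting by row/col.
#' @export
deformation_grid <- function(source, target, n_grid = 20L, magnify = 1,
                             pad = 0.1) {
  src <- if (inherits(source, "configuration")) source$points else
    as.matrix(source)
  tgt <- if (inherits(target, "configuration")) target$points else
    as.matrix(target)
  tgt <- src + magnify * (tgt - src)
  rx <- range(src[, 1L]); ry <- range(src[, 2L])
  rx <- rx + c(-1, 1) * pad * diff(rx)
  ry <- ry + c(-1, 1) * pad * diff(ry)
  g <- expand.grid(x = seq(rx[1L], rx[2L], length.out = n_grid),
                   y = seq(ry[1L], ry[2L], length.out = n_grid))
  warped <- tps_warp(src, tgt, as.matrix(g))
  data.frame(x = warped[, 1L], y = warped[, 2L],
             row = rep(seq_len(n_grid), each = n_grid),
             col = rep(seq_len(n_grid), times = n_grid))
}
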