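#' Per-genus consensus configurations
#'
#' Runs a generalized Procrustes superimposition within each genus and
#' returns each genus's consensus; a monotypic genus returns its single
#' normalized configuration. The genus means are intended to be
#' superimposed together (a second [gpa()]) before any cross-genus
#' analysis, mirroring the average-then-compare workflow.
#'
#' @param configs List of [configuration()]s.
#' @param genera Character vector of genus labels, one per configuration.
#' @param ... Passed to [gpa()].
#' @return Named list (genus -> [configuration()]) in order of first
#'   appearance.
#' @export
genus_consensus <- function(configs, genera, ...) {
  if (length(configs) != length(genera)) {
    stop("one genus label per configuration required")
  }
  if (any(!nzchar(genera) | is.na(genera))) stop("empty genus label")
  out <- list()
  for (g in unique(genera)) {
    members <- configs[genera == g]
    fit <- gpa(members, ...)
    cons <- fit$consensus
    cons$specimen_id <- g
    out[[g]] <- cons
  }
  out
}

#' Relative warps analysis
#'
#' Assembles the weight matrix from the tangent-space residuals of each
#' configuration about the consensus and decomposes it by singular-value
#' decomposition. With `alpha = 0` (the default) the residuals enter
#' unweighted -- uniform and non-uniform variation together -- and the
#' analysis is exactly a principal component analysis of tangent
#' coordinates. With `alpha != 0`, the non-affine part of each residual is
#' re-expressed in the principal-warp basis of the consensus and each
#' partial warp is scaled by its bending-energy eigenvalue to the power
#' `-alpha/2` (the affine part is left unscaled), emphasising large-scale
#' (`alpha > 0`) or small-scale (`alpha < 0`) deformation.
#'
#' Axis signs are fixed by making the largest-magnitude loading of each
#' warp vector positive, for run-to-run reproducibility.
#'
#' @param aligned_set Result of [gpa()] on at least 3 configurations
#'   (specimens or genus means).
#' @param alpha Warp-weight exponent; default 0.
#' @return Object of class `"relative_warps"`: list with `alpha`,
#'   `weight_matrix` (n x 2k, column-centered), `singular_values`
#'   (decreasing), `percent_variance` (sums to 100), `scores` (n x r, rows
#'   labelled), `warp_vectors` (2k x r right singular vectors) and
#'   `labels`.
#' @export
relative_warps <- function(aligned_set, alpha = 0) {
  stopifnot(inherits(aligned_set, "aligned_set"))
  n <- length(aligned_set$aligned)
  if (n < 3L) stop("relative warps needs at least 3 configurations")
  k <- nrow(aligned_set$consensus$points)
  tang <- tangent_project(aligned_set)
  W <- t(vapply(tang, config_vec, numeric(2L * k)))
  if (alpha != 0) {
    be <- bending_energy(aligned_set$consensus)
    lam <- be$eigenvalues
    nz <- lam > max(lam) * 1e-8
    w <- ifelse(nz, lam^(-alpha / 2), 1)
    # scaling operator expressed in landmark coordinates, per axis
    S <- be$principal_warps %*% (w * t(be$principal_warps))
    S2 <- rbind(cbind(S, matrix(0, k, k)), cbind(matrix(0, k, k), S))
    W <- W %*% S2
  }
  W <- sweep(W, 2L, colMeans(W))
  sv <- svd(W)
  keep <- sv$d > max(sv$d, 0) * 1e-10
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  # sign convention: largest-|loading| entry of each warp vector positive
  for (j in seq_along(d)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  scores <- U %*% diag(d, length(d))
  labels <- vapply(aligned_set$aligned, `[[`, "", "specimen_id")
  rownames(scores) <- labels
  colnames(scores) <- paste0("RW", seq_along(d))
  pv <- 100 * d^2 / sum(d^2)
  structure(list(alpha = alpha, weight_matrix = W, singular_values = d,
                 percent_variance = pv, scores = scores, warp_vectors = V,
                 labels = labels),
            class = "relative_warps")
}

#' @export
print.relative_warps <- function(x, ...) {
  cat(sprintf("<relative_warps: %d configurations, alpha = %g>\n",
              nrow(x$scores), x$alpha))
  pv <- utils::head(x$percent_variance, 4L)
  cat("  % variance:", paste(sprintf("%.2f", pv), collapse = ", "), "...\n")
  invisible(x)
}

#' Quadrant of a 2-D ordination score
#'
#' Sign-based quadrant of an (RW1, RW2) pair; exact zeros map to `"axis"`.
#'
#' @param score2d Numeric vector of length 2.
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`, `"axis"`.
#' @export
quadrant_of <- function(score2d) {
  x <- score2d[1L]; y <- score2d[2L]
  if (x == 0 || y == 0) return("axis")
  if (x > 0 && y > 0) "I" else if (x < 0 && y > 0) "II"
  else if (x < 0 && y < 0) "III" else "IV"
}

#' Principal-coordinates analysis of a distance matrix
#'
#' Classical metric multidimensional scaling: the matrix `-D^2/2` is double
#' centered and eigen-decomposed; axis scores are eigenvectors scaled by
#' the square roots of their (positive) eigenvalues. Axes with negative
#' eigenvalues are reported but dropped from the scores.
#'
#' @param distmat Labelled square distance matrix (e.g. from
#'   [distance_matrix()]).
#' @param n_axes Number of ordination axes requested.
#' @return Object of class `"pcoa"`: list with `axis_scores` (labels x
#'   axes, columns centered), `eigenvalues` (all, decreasing) and
#'   `n_positive`.
#' @export
pcoa <- function(distmat, n_axes) {
  m <- as.matrix(distmat)
  n <- nrow(m)
  if (n_axes > n - 1L) stop("n_axes must be at most n - 1")
  if (all(m == 0)) {
    scores <- matrix(0, n, n_axes,
                     dimnames = list(rownames(m), paste0("Axis",
                                                         seq_len(n_axes))))
    return(structure(list(axis_scores = scores,
                          eigenvalues = rep(0, n), n_positive = 0L),
                     class = "pcoa"))
  }
  fit <- stats::cmdscale(stats::as.dist(m), k = n - 1L, eig = TRUE)
  eig <- fit$eig
  npos <- sum(eig > max(abs(eig)) * 1e-12)
  if (n_axes > npos) {
    warning(sprintf("only %d positive eigenvalues; returning %d axes",
                    npos, npos))
    n_axes <- npos
  }
  scores <- fit$points[, seq_len(n_axes), drop = FALSE]
  rownames(scores) <- rownames(m)
  colnames(scores) <- paste0("Axis", seq_len(n_axes))
  structure(list(axis_scores = scores, eigenvalues = eig,
                 n_positive = npos),
            class = "pcoa")
}
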