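#' Construct a polyline
#'
#' A polyline is an ordered 2-D digitized curve, open or closed -- the raw
#' trace of a pronotum outline. A closed polyline does not repeat its first
#' vertex at the end; closure is implicit.
#'
#' @param vertices Numeric matrix with two columns (x, y) and at least two
#'   rows, or a two-column data frame.
#' @param closed Logical; is the curve closed?
#' @return An object of class `"polyline"`: a list with elements `vertices`
#'   (n x 2 matrix) and `closed`.
#' @examples
#' sq <- polyline(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), closed = TRUE)
#' arc_length(sq)
#' @export
polyline <- function(vertices, closed = TRUE) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stop("polyline vertices must have two columns (x, y)")
  if (nrow(vertices) < 2L) stop("polyline needs at least two vertices")
  storage.mode(vertices) <- "double"
  if (anyNA(vertices)) stop("polyline vertices contain NA")
  dup <- rowSums((vertices[-1L, , drop = FALSE] -
                  vertices[-nrow(vertices), , drop = FALSE])^2) == 0
  if (any(dup)) stop("consecutive duplicate vertices are forbidden")
  if (closed && all(vertices[1L, ] == vertices[nrow(vertices), ])) {
    stop("a closed polyline must not repeat its first vertex at the end")
  }
  dimnames(vertices) <- list(NULL, c("x", "y"))
  structure(list(vertices = vertices, closed = isTRUE(closed)),
            class = "polyline")
}

#' @export
print.polyline <- function(x, ...) {
  cat(sprintf("<polyline: %d vertices, %s, length %.6g>\n",
              nrow(x$vertices), if (x$closed) "closed" else "open",
              arc_length(x)))
  invisible(x)
}

segment_lengths <- function(curve) {
  v <- curve$vertices
  if (curve$closed) v <- rbind(v, v[1L, ])
  d <- diff(v)
  sqrt(rowSums(d^2))
}

#' Total arc length of a polyline
#'
#' Sum of Euclidean segment lengths; for closed curves the closing segment
#' back to the first vertex is included.
#'
#' @param curve A [polyline()].
#' @return Non-negative numeric scalar.
#' @export
arc_length <- function(curve) {
  stopifnot(inherits(curve, "polyline"))
  sum(segment_lengths(curve))
}

#' Signed area of a closed polyline
#'
#' Shoelace formula; positive for counter-clockwise traversal.
#'
#' @param curve A closed [polyline()].
#' @return Numeric scalar.
#' @export
signed_area <- function(curve) {
  stopifnot(inherits(curve, "polyline"))
  if (!curve$closed) stop("signed area is defined for closed polylines only")
  v <- curve$vertices
  v2 <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE])
  sum(v[, 1L] * v2[, 2L] - v2[, 1L] * v[, 2L]) / 2
}

#' Normalize traversal direction to counter-clockwise
#'
#' Outline correspondence across specimens requires a consistent traversal
#' direction; this orients a closed curve counter-clockwise by the
#' signed-area test, keeping the start vertex fixed.
#'
#' @param curve A closed [polyline()].
#' @return A new [polyline()]; the input is not modified.
#' @export
normalize_traversal <- function(curve) {
  stopifnot(inherits(curve, "polyline"))
  if (!curve$closed) stop("normalize_traversal requires a closed polyline")
  a <- signed_area(curve)
  if (a == 0) stop("degenerate closed curve: signed area is zero")
  if (a > 0) return(curve)
  v <- curve$vertices
  # reverse order but keep the same start vertex
  polyline(v[c(1L, nrow(v):2L), , drop = FALSE], closed = TRUE)
}

#' Resample a polyline at equal arc-length spacing
#'
#' Places `k` semilandmarks on the curve at equal arc-length intervals,
#' measured from a chosen start vertex along the stored vertex order. For a
#' closed curve the points sit at arc positions i*L/k (i = 0..k-1), so no
#' endpoint is duplicated; for an open curve at i*L/(k-1), retaining both
#' endpoints. Points lie exactly on the polyline (linear interpolation
#' within segments).
#'
#' @param curve A [polyline()] of positive length.
#' @param k Number of semilandmarks (>= 3). The study convention is 50.
#' @param start_vertex_index Index of the vertex where arc length zero is
#'   anchored (closed curves only; open curves always start at vertex 1).
#' @param specimen_id Optional id attached to the returned configuration.
#' @return A [configuration()] of k points.
#' @export
resample_equidistant <- function(curve, k, start_vertex_index = 1L,
                                 specimen_id = NA_character_) {
  stopifnot(inherits(curve, "polyline"))
  k <- as.integer(k)
  if (k < 3L) stop("k must be at least 3")
  v <- curve$vertices
  n <- nrow(v)
  if (curve$closed) {
    if (start_vertex_index < 1L || start_vertex_index > n) {
      stop("start_vertex_index out of range")
    }
    if (start_vertex_index != 1L) {
      v <- v[c(start_vertex_index:n, 1L:(start_vertex_index - 1L)), ,
             drop = FALSE]
    }
    v <- rbind(v, v[1L, ])
  } else if (start_vertex_index != 1L) {
    stop("open curves are resampled from their first vertex")
  }
  seg <- sqrt(rowSums(diff(v)^2))
  L <- sum(seg)
  if (L <= 0) stop("degenerate curve: zero arc length")
  cum <- c(0, cumsum(seg))
  targets <- if (curve$closed) (seq_len(k) - 1L) * L / k else
    (seq_len(k) - 1L) * L / (k - 1L)
  idx <- findInterval(targets, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seg))
  frac <- (targets - cum[idx]) / seg[idx]
  pts <- v[idx, , drop = FALSE] + frac * (v[idx + 1L, , drop = FALSE] -
                                          v[idx, , drop = FALSE])
  configuration(pts, specimen_id = specimen_id)
}

#' Cyclically align a closed-outline configuration to a reference
#'
#' When outlines were not digitized from a homologous start point, the
#' correspondence of semilandmarks is only defined up to a cyclic shift.
#' This picks, for one configuration, the cyclic relabelling of its points
#' that minimizes the partial Procrustes distance to a reference.
#'
#' @param config A [configuration()] of k points taken around a closed
#'   outline.
#' @param reference A [configuration()] with the same k.
#' @return A list with `config` (the shifted configuration), `shift`
#'   (0-based shift applied) and `distance` (the minimized partial
#'   Procrustes distance).
#' @export
cyclic_align <- function(config, reference) {
  stopifnot(inherits(config, "configuration"),
            inherits(reference, "configuration"))
  k <- nrow(config$points)
  if (k != nrow(reference$points)) stop("landmark counts differ")
  best <- NULL
  for (s in 0L:(k - 1L)) {
    ord <- ((seq_len(k) - 1L + s) %% k) + 1L
    cand <- configuration(config$points[ord, , drop = FALSE],
                          specimen_id = config$specimen_id)
    d <- align_pair(cand, reference)$distance
    if (is.null(best) || d < best$distance) {
      best <- list(config = cand, shift = s, distance = d)
    }
  }
  best
}
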