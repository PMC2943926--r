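#' Pairwise Procrustes distance matrix
#'
#' Partial Procrustes distances (the square root of the sum of squared
#' differences between corresponding points of optimally superimposed,
#' unit-size configurations) between every unordered pair, via
#' [align_pair()].
#'
#' @param consensuses Named list of [configuration()]s (e.g. the output of
#'   [genus_consensus()]); names become the matrix labels.
#' @param allow_reflection Passed to [align_pair()].
#' @return Square symmetric matrix with zero diagonal and dimnames.
#' @export
distance_matrix <- function(consensuses, allow_reflection = FALSE) {
  n <- length(consensuses)
  if (n < 2L) stop("need at least 2 configurations")
  labels <- names(consensuses)
  if (is.null(labels)) {
    labels <- vapply(consensuses, `[[`, "", "specimen_id")
  }
  ks <- vapply(consensuses, function(cc) nrow(cc$points), 0L)
  if (length(unique(ks)) != 1L) stop("landmark counts differ")
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <-
        align_pair(consensuses[[i]], consensuses[[j]],
                   allow_reflection)$distance
    }
  }
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Unweighted pair-group method with arithmetic averages: the pair of
#' clusters with the smallest average inter-cluster distance is merged at
#' height d/2, and distances to the merged cluster are updated as
#' size-weighted arithmetic means (UPGMA proper, not WPGMA). Ties are
#' broken by the lexicographically smallest pair of cluster indices, so
#' the result is deterministic. Heights are reported as half the fusion
#' distance, so the root-to-leaf path equals half the cophenetic distance.
#'
#' @param distmat Labelled square symmetric distance matrix, n >= 2.
#' @return Object of class `"upgma_tree"`: list with `labels`, `merge`
#'   (n-1 x 2 matrix, hclust convention: negative entries index leaves,
#'   positive entries earlier merges) and `heights` (non-decreasing merge
#'   heights).
#' @export
upgma <- function(distmat) {
  m <- as.matrix(distmat)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 taxa")
  if (!isTRUE(all.equal(m, t(m))) || any(diag(m) != 0) || any(m < 0)) {
    stop("not a valid distance matrix")
  }
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # active clusters: id (negative leaf / positive merge), size
  ids <- -seq_len(n)
  sizes <- rep(1L, n)
  D <- m
  merge <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)
  minleaves <- integer(n - 1L)
  for (step in seq_len(n - 1L)) {
    nact <- nrow(D)
    best <- c(1L, 2L)
    bestd <- Inf
    for (i in seq_len(nact - 1L)) {
      for (j in (i + 1L):nact) {
        if (D[i, j] < bestd) { bestd <- D[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    # child with the smallest contained leaf index first, so printed trees
    # are deterministic and two-leaf trees read (first, second)
    minleaf <- function(id) if (id < 0L) -id else minleaves[id]
    pair <- c(ids[i], ids[j])
    if (minleaf(pair[2L]) < minleaf(pair[1L])) pair <- pair[2:1]
    merge[step, ] <- pair
    minleaves[step] <- min(minleaf(pair[1L]), minleaf(pair[2L]))
    heights[step] <- bestd / 2
    ni <- sizes[i]; nj <- sizes[j]
    newrow <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(nact), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newrow[keep]),
               c(newrow[keep], 0))
    ids <- c(ids[keep], step)
    sizes <- c(sizes[keep], ni + nj)
  }
  structure(list(labels = labels, merge = merge, heights = heights),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree: %d leaves, height %.6g>\n",
              length(x$labels), max(x$heights)))
  invisible(x)
}

#' Cophenetic distance matrix of a UPGMA tree
#'
#' The cophenetic distance between two leaves is twice the height of the
#' merge at which they first join one cluster; for a tree built by
#' [upgma()] from an ultrametric matrix this recovers the input exactly.
#'
#' @param tree An `"upgma_tree"`.
#' @return Labelled square symmetric matrix.
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  n <- length(tree$labels)
  coph <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  members <- lapply(seq_len(n), identity)  # leaf sets per merge id
  leafset <- function(id) if (id < 0L) -id else members[[id]]
  for (step in seq_len(n - 1L)) {
    a <- leafset(tree$merge[step, 1L])
    b <- leafset(tree$merge[step, 2L])
    coph[a, b] <- coph[b, a] <- 2 * tree$heights[step]
    members[[step]] <- c(a, b)
  }
  coph
}

#' Cophenetic correlation between a phenogram and its source matrix
#'
#' Pearson correlation between the original distances and the cophenetic
#' distances over all unordered pairs -- the standard diagnostic of how
#' faithfully a UPGMA phenogram represents a distance matrix.
#'
#' @param tree An `"upgma_tree"`.
#' @param distmat The distance matrix the tree was built from (same label
#'   set, any order).
#' @return Correlation in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(tree, distmat) {
  m <- as.matrix(distmat)
  if (length(tree$labels) < 3L) {
    stop("cophenetic correlation undefined for fewer than 3 leaves")
  }
  if (!setequal(rownames(m), tree$labels)) stop("label sets differ")
  m <- m[tree$labels, tree$labels]
  coph <- cophenetic_matrix(tree)
  ut <- upper.tri(m)
  stats::cor(m[ut], coph[ut])
}

quote_newick_label <- function(lab) {
  if (grepl("[][(),:;'[:space:]]", lab)) {
    paste0("'", gsub("'", "''", lab), "'")
  } else lab
}

#' Serialize a UPGMA tree to a Newick string
#'
#' Branch lengths are height differences, so every root-to-leaf path
#' length equals the tree height. Labels containing Newick-reserved
#' characters are single-quoted.
#'
#' @param tree An `"upgma_tree"`, or a single-leaf tree expressed as a
#'   character label.
#' @return Newick string terminated by `";"`.
#' @export
to_newick <- function(tree) {
  if (is.character(tree) && length(tree) == 1L) {
    return(paste0(quote_newick_label(tree), ";"))
  }
  stopifnot(inherits(tree, "upgma_tree"))
  node_str <- function(id, parent_height) {
    if (id < 0L) {
      return(sprintf("%s:%.17g", quote_newick_label(tree$labels[-id]),
                     parent_height))
    }
    h <- tree$heights[id]
    sprintf("(%s,%s):%.17g", node_str(tree$merge[id, 1L], h),
            node_str(tree$merge[id, 2L], h), parent_height - h)
  }
  root <- nrow(tree$merge)
  h <- tree$heights[root]
  paste0("(", node_str(tree$merge[root, 1L], h), ",",
         node_str(tree$merge[root, 2L], h), ");")
}

#' Write a tree to a Newick file
#'
#' @param tree An `"upgma_tree"` (or single leaf label, for degenerate
#'   one-taxon trees).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  writeLines(to_newick(tree), path)
  invisible(path)
}
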