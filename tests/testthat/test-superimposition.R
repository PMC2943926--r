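test_that("centroid size matches its definition and scaling laws", {
  sq <- configuration(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  expect_equal(centroid_size(sq), sqrt(2))
  set.seed(31)
  cfg <- random_config(9L)
  expect_equal(centroid_size(configuration(cfg$points * 3.7)),
               3.7 * centroid_size(cfg))
  expect_equal(centroid_size(configuration(sweep(cfg$points, 2L, c(5, -2),
                                                 `+`))),
               centroid_size(cfg))
  expect_error(centroid_size(matrix(1, 4L, 2L)), "coincident")
})

test_that("align_pair removes similarity transforms and matches the grid oracle", {
  set.seed(32)
  cfg <- random_config(10L)
  self <- align_pair(cfg, cfg)
  expect_equal(self$distance, 0, tolerance = 1e-12)
  expect_equal(self$rotation, diag(2), tolerance = 1e-9)
  expect_lt(align_pair(random_similarity(cfg), cfg)$distance, 1e-9)

  tri1 <- configuration(rbind(c(0, 0), c(1, 0), c(0, 1)))
  tri2 <- configuration(rbind(c(0, 0), c(1, 0), c(0, 2)))
  expect_equal(align_pair(tri1, tri2)$distance,
               grid_procrustes_distance(tri1, tri2), tolerance = 1e-6)

  for (i in 1:10) {
    a <- random_config(8L); b <- random_config(8L)
    expect_equal(align_pair(a, b)$distance, grid_procrustes_distance(a, b),
                 tolerance = 1e-6)
  }
  expect_error(align_pair(random_config(5L), random_config(6L)),
               "landmark counts")
})

test_that("reflection handling: mirrored shapes align only when allowed", {
  set.seed(33)
  cfg <- random_config(9L)
  mir <- configuration(cbind(-cfg$points[, 1L], cfg$points[, 2L]))
  expect_lt(align_pair(mir, cfg, allow_reflection = TRUE)$distance, 1e-9)
  expect_gt(align_pair(mir, cfg, allow_reflection = FALSE)$distance, 0.1)
  expect_equal(det(align_pair(mir, cfg, allow_reflection = FALSE)$rotation),
               1, tolerance = 1e-9)
})

test_that("partial and geodesic distances behave as metrics", {
  expect_equal(geodesic_distance(0), 0)
  expect_equal(geodesic_distance(2), pi)
  expect_equal(geodesic_distance(sqrt(2)), pi / 2)
  expect_error(geodesic_distance(2.1), "\\[0, 2\\]")
  set.seed(34)
  configs <- replicate(12L, random_config(7L), simplify = FALSE)
  n <- length(configs)
  d <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dij <- procrustes_distance(configs[[i]], configs[[j]])
    dji <- procrustes_distance(configs[[j]], configs[[i]])
    expect_equal(dij, dji, tolerance = 1e-10)
    d[i, j] <- d[j, i] <- geodesic_distance(dij)
  }
  triples <- utils::combn(n, 3L)
  for (t in seq_len(ncol(triples))) {
    ijk <- triples[, t]
    expect_lte(d[ijk[1], ijk[3]],
               d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + 1e-9)
  }
})

test_that("gpa centers, normalizes and converges; trivial cases", {
  set.seed(35)
  single <- gpa(list(random_config(8L)))
  expect_true(single$converged)
  expect_equal(single$consensus$points, single$aligned[[1]]$points,
               tolerance = 1e-12)
  # copies of one shape under random similarity transforms collapse
  base <- random_config(10L)
  copies <- replicate(6L, random_similarity(base), simplify = FALSE)
  fit <- gpa(copies)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_lt(procrustes_distance(fit$aligned[[i]], fit$aligned[[j]]), 1e-8)
  }
  for (cfg in fit$aligned) {
    expect_lt(max(abs(colMeans(cfg$points))), 1e-9)
    expect_equal(sqrt(sum(cfg$points^2)), 1, tolerance = 1e-9)
  }
  # consensus is the renormalized mean of the aligned configurations
  mn <- Reduce(`+`, lapply(fit$aligned, `[[`, "points")) / 6
  mn <- sweep(mn, 2L, colMeans(mn))
  expect_equal(mn / sqrt(sum(mn^2)), fit$consensus$points,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(gpa(list()), "at least one")
})

test_that("gpa distances are invariant to similarity transforms and order", {
  set.seed(36)
  configs <- replicate(10L, random_config(9L), simplify = FALSE)
  pairdists <- function(fit) {
    n <- length(fit$aligned)
    out <- numeric(0)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      out <- c(out, procrustes_distance(fit$aligned[[i]],
                                        fit$aligned[[j]]))
    }
    out
  }
  d0 <- pairdists(gpa(configs))
  transformed <- lapply(configs, random_similarity)
  expect_equal(pairdists(gpa(transformed)), d0, tolerance = 1e-6)
  perm <- sample(10L)
  dperm <- pairdists(gpa(configs[perm]))
  # compare as distance matrices under the permutation
  to_mat <- function(v, n) { m <- matrix(0, n, n); m[lower.tri(m)] <- v;
                             m + t(m) }
  expect_equal(to_mat(dperm, 10L), to_mat(d0, 10L)[perm, perm],
               tolerance = 1e-6)
})

test_that("tangent projection is orthogonal to the consensus with norm sin(rho)", {
  set.seed(37)
  base <- random_config(15L)
  configs <- lapply(1:6, function(i) {
    configuration(base$points + matrix(stats::rnorm(30L, 0, 0.05), ncol = 2L))
  })
  fit <- gpa(configs)
  z <- as.numeric(fit$consensus$points)
  tang <- tangent_project(fit)
  cons_t <- as.numeric(fit$consensus$points) -
    z * sum(z * as.numeric(fit$consensus$points)) / sum(z^2)
  expect_lt(max(abs(cons_t)), 1e-12)
  for (i in seq_along(tang)) {
    expect_lt(abs(sum(as.numeric(tang[[i]]) * z)), 1e-10)
    rho <- geodesic_distance(procrustes_distance(fit$aligned[[i]],
                                                 fit$consensus))
    Y <- sqrt(sum(tang[[i]]^2))
    expect_equal(Y, sin(rho), tolerance = 1e-9)
    expect_lte(abs(Y - rho), rho^3 / 6 + 1e-9)
  }
})

test_that("tangent-space diagnostic approaches 1 for small shape variation", {
  set.seed(38)
  base <- preshape(random_config(25L))
  configs <- lapply(1:15, function(i) {
    noise <- matrix(stats::rnorm(50L), ncol = 2L)
    noise <- noise / sqrt(sum(noise^2)) * stats::runif(1L, 0, 0.01)
    random_similarity(configuration(base + noise))
  })
  fit <- gpa(configs)
  tt <- tangent_space_test(fit)
  expect_gte(tt$uncentred_correlation, 0.9999)
  expect_equal(tt$slope_through_origin, 1, tolerance = 1e-3)
  expect_length(tt$geodesic_distances, 15L)
  expect_length(tt$tangent_distances, 15L)
  # uncentred correlation of a vector with itself is 1
  r <- sum(tt$geodesic_distances^2) /
    sqrt(sum(tt$geodesic_distances^2) * sum(tt$geodesic_distances^2))
  expect_equal(r, 1)
  # identical specimens make the diagnostic undefined
  same <- replicate(4L, configuration(base), simplify = FALSE)
  expect_error(tangent_space_test(gpa(same)), "identical")
})
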