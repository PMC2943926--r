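test_that("genus consensus averages within genera and keeps one entry per genus", {
  set.seed(51)
  base <- preshape(random_config(10L))
  # a pair exactly symmetric about a mean preshape returns that mean;
  # the offset must be a genuine shape-space tangent vector, i.e.
  # orthogonal to the mean and to its rotation direction
  w <- matrix(stats::rnorm(20L), ncol = 2L)
  w <- w - rep(colMeans(w), each = 10L)
  w <- w - base * sum(base * w)
  jb <- cbind(-base[, 2L], base[, 1L])
  w <- w - jb * sum(jb * w) / sum(jb^2)
  w <- w / sqrt(sum(w^2))
  t0 <- 0.1
  pair <- list(configuration(cos(t0) * base + sin(t0) * w),
               configuration(cos(t0) * base - sin(t0) * w))
  cons <- genus_consensus(pair, c("G", "G"))
  expect_length(cons, 1L)
  expect_lt(procrustes_distance(cons$G, configuration(base)), 1e-8)
  # monotypic genus: consensus is the normalized member itself
  solo <- configuration(base * 3 + 1)
  cons1 <- genus_consensus(list(solo), "M")
  expect_lt(procrustes_distance(cons1$M, solo), 1e-9)
  # invariant to within-genus specimen order
  set.seed(52)
  members <- lapply(1:4, function(i)
    configuration(base + matrix(stats::rnorm(20L, 0, 0.03), ncol = 2L)))
  c1 <- genus_consensus(members, rep("G", 4L))$G
  c2 <- genus_consensus(members[c(3, 1, 4, 2)], rep("G", 4L))$G
  expect_lt(procrustes_distance(c1, c2), 1e-6)
  expect_error(genus_consensus(members, rep("", 4L)), "empty")
})

test_that("relative warps with alpha = 0 equals PCA of tangent coordinates", {
  set.seed(53)
  base <- preshape(random_config(14L))
  configs <- lapply(1:10, function(i)
    random_similarity(configuration(base + matrix(stats::rnorm(28L, 0, 0.04),
                                                  ncol = 2L))))
  fit <- gpa(configs)
  rw <- relative_warps(fit, alpha = 0)
  expect_equal(sum(rw$percent_variance), 100, tolerance = 1e-6)
  # covariance-eigen oracle on the same tangent residuals
  W <- t(vapply(tangent_project(fit), as.numeric, numeric(28L)))
  W <- sweep(W, 2L, colMeans(W))
  ev <- eigen(stats::cov(W), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-10]
  expect_equal(100 * ev / sum(ev), rw$percent_variance, tolerance = 1e-8)
  # score columns are uncorrelated (orthogonal) and bounded in number
  S <- sweep(rw$scores, 2L, colMeans(rw$scores))
  cv <- crossprod(S)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  expect_lte(length(rw$singular_values), min(10 - 1, 2 * 14 - 4))
  expect_error(relative_warps(gpa(configs[1:2])), "at least 3")
})

test_that("a single planted shape mode captures all the variance on RW1", {
  set.seed(54)
  base <- preshape(random_config(12L))
  dirv <- matrix(stats::rnorm(24L), ncol = 2L)
  dirv <- dirv - rep(colMeans(dirv), each = 12L)
  dirv <- dirv / sqrt(sum(dirv^2))
  configs <- lapply(seq(-0.05, 0.05, length.out = 9L), function(t)
    configuration(base + t * dirv))
  rw <- relative_warps(gpa(configs))
  expect_gte(rw$percent_variance[1L], 99.9)
})

test_that("relative warps determinism: axis signs are reproducible", {
  set.seed(55)
  base <- preshape(random_config(10L))
  configs <- lapply(1:6, function(i)
    configuration(base + matrix(stats::rnorm(20L, 0, 0.05), ncol = 2L)))
  fit <- gpa(configs)
  rw1 <- relative_warps(fit)
  rw2 <- relative_warps(fit)
  expect_identical(rw1$scores, rw2$scores)
  for (j in seq_along(rw1$singular_values)) {
    i <- which.max(abs(rw1$warp_vectors[, j]))
    expect_gt(rw1$warp_vectors[i, j], 0)
  }
})

test_that("alpha reweighting changes emphasis but keeps a valid spectrum", {
  set.seed(56)
  base <- preshape(random_config(12L))
  configs <- lapply(1:8, function(i)
    configuration(base + matrix(stats::rnorm(24L, 0, 0.05), ncol = 2L)))
  fit <- gpa(configs)
  rw <- relative_warps(fit, alpha = 1)
  expect_equal(sum(rw$percent_variance), 100, tolerance = 1e-6)
  expect_true(all(diff(rw$singular_values) <= 1e-12))
})

test_that("quadrant assignment is sign-based with an axis escape", {
  expect_equal(quadrant_of(c(1, 1)), "I")
  expect_equal(quadrant_of(c(-1, 1)), "II")
  expect_equal(quadrant_of(c(-2, -3)), "III")
  expect_equal(quadrant_of(c(0.5, -1)), "IV")
  expect_equal(quadrant_of(c(0, 3)), "axis")
})

test_that("principal coordinates recover planted plane geometry", {
  set.seed(57)
  pts <- matrix(stats::rnorm(10L), 5L)
  m <- as.matrix(stats::dist(pts))
  dimnames(m) <- rep(list(paste0("p", 1:5)), 2L)
  ord <- pcoa(m, 2L)
  expect_lt(max(abs(colMeans(ord$axis_scores))), 1e-9)
  rec <- configuration(ord$axis_scores)
  expect_lt(align_pair(rec, configuration(pts),
                       allow_reflection = TRUE)$distance, 1e-6)
  # all-zero distances give all-zero scores
  z <- matrix(0, 4L, 4L, dimnames = rep(list(letters[1:4]), 2L))
  expect_true(all(pcoa(z, 2L)$axis_scores == 0))
  expect_error(pcoa(m, 5L), "at most")
})
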