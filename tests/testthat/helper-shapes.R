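# Shared fixtures and independent oracles for the test suite.

random_config <- function(k = 12L, id = "spec") {
  configuration(matrix(stats::rnorm(2L * k), ncol = 2L), specimen_id = id)
}

# Random similarity transform of a configuration (rotation, scale, shift).
random_similarity <- function(config) {
  ang <- stats::runif(1L, 0, 2 * pi)
  sc <- exp(stats::runif(1L, log(0.3), log(3)))
  tr <- stats::rnorm(2L, 0, 5)
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L, 2L)
  configuration(sweep(sc * (config$points %*% t(R)), 2L, tr, `+`),
                specimen_id = config$specimen_id)
}

unit_circle_polyline <- function(n = 1000L) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  polyline(cbind(cos(th), sin(th)), closed = TRUE)
}

# Independent brute-force rotation-grid oracle for the optimal-rotation
# distance: evaluates the rotation objective on a theta grid using the
# trigonometric expansion of the squared distance (no SVD involved).
grid_procrustes_distance <- function(moving, target, step = 1e-4) {
  center_unit <- function(p) {
    p <- sweep(p, 2L, colMeans(p))
    p / sqrt(sum(p^2))
  }
  X <- center_unit(moving$points)
  Y <- center_unit(target$points)
  A <- sum(Y[, 1L] * X[, 1L] + Y[, 2L] * X[, 2L])
  B <- sum(Y[, 2L] * X[, 1L] - Y[, 1L] * X[, 2L])
  theta <- seq(0, 2 * pi, by = step)
  sqrt(pmax(0, min(2 - 2 * (A * cos(theta) + B * sin(theta)))))
}

# Least-squares affine fit oracle for the thin-plate-spline affine case.
fit_affine <- function(src, tgt) {
  Xd <- cbind(1, src)
  coef <- solve(crossprod(Xd), crossprod(Xd, tgt))
  function(p) cbind(1, as.matrix(p)) %*% coef
}

# Genus tables for planted-recovery designs. Both are built from the
# packaged 13-genus design by rescaling genus means about the extant
# family centroid so the planted separation-to-scatter condition holds.
coeffs8 <- c("a1", "b1", "a2", "b2", "a3", "b3", "a4", "b4")

family_recovery_design <- function(seed) {
  d <- default_study_design(seed = seed, within_genus_sd = 0.004,
                            landmark_jitter_sd = 0.0005)
  g <- d$genera
  M <- as.matrix(g[, coeffs8])
  ext <- g$status == "extant"
  ctr <- colMeans(M[ext, ])
  M[ext, ] <- sweep(sweep(M[ext, , drop = FALSE], 2L, ctr) * 0.5, 2L,
                    ctr, `+`)
  M[!ext, ] <- sweep(sweep(M[!ext, , drop = FALSE], 2L, ctr) * 1.7, 2L,
                     ctr, `+`)
  d$genera[, coeffs8] <- M
  d
}

genus_recovery_design <- function(seed) {
  default_study_design(seed = seed, within_genus_sd = 0.001,
                       landmark_jitter_sd = 0.0005)
}

# Resample + superimpose a generated study; returns configs, genera,
# status, the specimen-level gpa fit.
study_fit <- function(design, k = 50L) {
  records <- generate_study(design)
  configs <- lapply(records, function(rec) {
    resample_equidistant(normalize_traversal(rec$curves[[1L]]), k,
                         specimen_id = rec$specimen_id)
  })
  list(records = records, configs = configs,
       genera = vapply(records, `[[`, "", "genus"),
       status = vapply(records, `[[`, "", "status"),
       fit = gpa(configs))
}

# Do the given labels form a clade in the UPGMA tree? True iff every
# within-group cophenetic distance is below every group-to-outside one.
is_clade <- function(tree, labels) {
  coph <- cophenetic_matrix(tree)
  inside <- rownames(coph) %in% labels
  if (sum(inside) < 2L) return(TRUE)
  max(coph[inside, inside]) < min(coph[inside, !inside])
}
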