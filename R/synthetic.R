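#' Closed outline from truncated Fourier radius coefficients
#'
#' Samples, at equal angles, the closed curve
#' `r(theta) = r0 * (1 + sum_h a_h cos(h theta) + b_h sin(h theta))`.
#' A truncated Fourier perturbation of a circle is a compact family that
#' covers the rounded-quadrate outlines typical of pronota; all-zero
#' coefficients give a circle of radius `r0`.
#'
#' @param coeffs Numeric vector of harmonic coefficients, interleaved
#'   `(a1, b1, a2, b2, ...)`; length `2 * H`.
#' @param n_vertices Number of vertices sampled (>= 16).
#' @param r0 Base radius.
#' @return A closed [polyline()].
#' @export
base_outline <- function(coeffs, n_vertices = 200L, r0 = 1) {
  n_vertices <- as.integer(n_vertices)
  if (n_vertices < 16L) stop("n_vertices must be at least 16")
  if (length(coeffs) %% 2L != 0L) stop("coeffs must interleave (a_h, b_h) pairs")
  H <- length(coeffs) / 2L
  a <- coeffs[seq(1L, by = 2L, length.out = H)]
  b <- coeffs[seq(2L, by = 2L, length.out = H)]
  theta <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  r <- rep(1, n_vertices)
  for (h in seq_len(H)) r <- r + a[h] * cos(h * theta) + b[h] * sin(h * theta)
  r <- r0 * r
  if (any(r <= 0)) stop("coefficients drive the radius non-positive")
  polyline(cbind(r * cos(theta), r * sin(theta)), closed = TRUE)
}

#' Construct a synthetic study design
#'
#' @param genera Data frame with columns `name`, `status` (`extant`/
#'   `fossil`), `n_species`, `species` (list-column or
#'   semicolon-separated epithets) and mean coefficient columns
#'   `a1, b1, ..., a4, b4`.
#' @param within_genus_sd SD of the per-coefficient Gaussian deviation of
#'   each species from its genus mean shape.
#' @param landmark_jitter_sd SD of per-vertex Gaussian digitizing jitter,
#'   in units of the base radius.
#' @param nuisance Apply a random similarity transform (rotation, scale,
#'   translation) to each outline?
#' @param k_semilandmarks Semilandmark count downstream analyses will use.
#' @param n_vertices Vertices per generated outline.
#' @param seed Integer seed; the design is fully reproducible from it.
#' @return Object of class `"study_design"`.
#' @export
study_design <- function(genera, within_genus_sd = 0.008,
                         landmark_jitter_sd = 0.002, nuisance = TRUE,
                         k_semilandmarks = 50L, n_vertices = 200L,
                         seed = 1L) {
  stopifnot(is.data.frame(genera),
            all(c("name", "status", "n_species") %in% names(genera)))
  if (any(genera$n_species < 1L)) stop("each genus needs at least 1 species")
  if (within_genus_sd < 0 || landmark_jitter_sd < 0) stop("sds must be >= 0")
  structure(list(genera = genera, within_genus_sd = within_genus_sd,
                 landmark_jitter_sd = landmark_jitter_sd,
                 nuisance = isTRUE(nuisance),
                 k_semilandmarks = as.integer(k_semilandmarks),
                 n_vertices = as.integer(n_vertices),
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Default study design: 13 genera, 28 species
#'
#' Reads the design constants shipped with the package: eight monotypic
#' fossil genera plus five extant genera holding 10, 5, 3, 1 and 1
#' species (28 outlines in 13 genera, 20 of them extant). The five extant
#' genus mean shapes are drawn from one compact shape family while the
#' fossil means are dispersed, emulating the qualitative structure of the
#' real pronotum data.
#'
#' @param ... Overrides passed to [study_design()] (e.g. `seed`,
#'   `within_genus_sd`).
#' @return A [study_design()].
#' @export
default_study_design <- function(...) {
  path <- system.file("extdata", "study_design.yaml", package = "pronomorph",
                      mustWork = TRUE)
  design_from_yaml(path, ...)
}

#' Load a study design from a YAML file
#'
#' @param path YAML file with a `genera` list (each entry: `name`,
#'   `status`, `species` list, `coeffs` of 8 numbers) and optional
#'   top-level defaults (`within_genus_sd`, `landmark_jitter_sd`,
#'   `nuisance`, `k_semilandmarks`, `n_vertices`, `seed`).
#' @param ... Overrides of the file's top-level settings.
#' @return A [study_design()].
#' @export
design_from_yaml <- function(path, ...) {
  y <- yaml::read_yaml(path)
  genera <- do.call(rbind, lapply(y$genera, function(g) {
    co <- as.numeric(g$coeffs)
    stopifnot(length(co) == 8L)
    df <- data.frame(name = g$name, status = g$status,
                     n_species = length(g$species))
    df$species <- list(as.character(g$species))
    cf <- as.data.frame(as.list(co))
    names(cf) <- c("a1", "b1", "a2", "b2", "a3", "b3", "a4", "b4")
    cbind(df, cf)
  }))
  args <- list(genera = genera)
  for (key in c("within_genus_sd", "landmark_jitter_sd", "nuisance",
                "k_semilandmarks", "n_vertices", "seed")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  over <- list(...)
  args[names(over)] <- over
  do.call(study_design, args)
}

coeff_cols <- c("a1", "b1", "a2", "b2", "a3", "b3", "a4", "b4")

# One RNG substream per record, derived from the design seed by counter,
# so a record's outline does not depend on generation order.
record_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * i) %% 2147483647)
}

#' Generate a synthetic outline study
#'
#' For each genus, draws `n_species` outlines whose Fourier coefficients
#' are the genus mean plus independent Gaussian deviations
#' (`within_genus_sd` per coefficient), builds each outline with
#' [base_outline()], optionally jitters every vertex (Gaussian,
#' `landmark_jitter_sd`) and, when `nuisance` is on, applies a random
#' similarity transform: rotation U(0, 2pi), scale log-uniform on
#' (0.5, 2), translation U(-10, 10) per axis. Records carry genus,
#' species and extant/fossil status, and the whole data set is a
#' deterministic function of the design seed.
#'
#' @param design A [study_design()].
#' @return List of [specimen_record()], one per species outline.
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  g <- design$genera
  records <- list()
  idx <- 0L
  for (gi in seq_len(nrow(g))) {
    mean_co <- as.numeric(g[gi, coeff_cols])
    sp_names <- if (!is.null(g$species)) g$species[[gi]] else
      paste0("sp", seq_len(g$n_species[gi]))
    for (si in seq_len(g$n_species[gi])) {
      idx <- idx + 1L
      set.seed(record_seed(design$seed, idx))
      co <- mean_co + stats::rnorm(8L, 0, design$within_genus_sd)
      pl <- base_outline(co, n_vertices = design$n_vertices)
      v <- pl$vertices
      if (design$landmark_jitter_sd > 0) {
        v <- v + matrix(stats::rnorm(length(v), 0,
                                     design$landmark_jitter_sd),
                        ncol = 2L)
      }
      if (design$nuisance) {
        ang <- stats::runif(1L, 0, 2 * pi)
        sc <- exp(stats::runif(1L, log(0.5), log(2)))
        tr <- stats::runif(2L, -10, 10)
        R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L, 2L)
        v <- sweep(sc * (v %*% t(R)), 2L, tr, `+`)
      }
      sp <- if (si <= length(sp_names)) sp_names[si] else paste0("sp", si)
      records[[idx]] <- specimen_record(
        specimen_id = sprintf("%s_%s", g$name[gi], sp),
        genus = g$name[gi], species = sp, status = g$status[gi],
        curves = list(polyline(v, closed = TRUE)))
    }
  }
  records
}

#' Labels table for generated records
#'
#' @param records List of [specimen_record()].
#' @return Data frame with columns `specimen_id`, `genus`, `species`,
#'   `status`.
#' @export
study_labels <- function(records) {
  data.frame(specimen_id = vapply(records, `[[`, "", "specimen_id"),
             genus = vapply(records, `[[`, "", "genus"),
             species = vapply(records, `[[`, "", "species"),
             status = vapply(records, `[[`, "", "status"))
}
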