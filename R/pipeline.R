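#' Run the full pronotum-morphometrics workflow
#'
#' Orchestrates the whole analysis in order: outline input (read from TPS
#' or simulated), traversal normalization, arc-length semilandmark
#' resampling, generalized Procrustes superimposition of all specimens,
#' the tangent-space approximation diagnostic, per-genus consensus shapes,
#' a second superimposition of the genus means, relative warps with
#' quadrant assignment, the genus-level Procrustes distance matrix,
#' principal-coordinates ordination, and the UPGMA phenogram with its
#' cophenetic correlation. All tabular outputs are written under
#' `config$outdir` and the run is a deterministic function of the
#' configuration (including the seed of a simulate block).
#'
#' @param config A named list (or path to a YAML file holding one) with
#'   elements:
#'   \describe{
#'     \item{simulate}{optional list: `design` (YAML path; default the
#'       packaged 13-genus design) plus any [study_design()] overrides
#'       such as `seed`, `within_genus_sd`, `nuisance`.}
#'     \item{input}{alternatively, list with `tps` and `labels` (CSV)
#'       paths.}
#'     \item{k}{semilandmarks per outline (default 50).}
#'     \item{cyclic_align}{`"off"` (default; the digitized start vertex is
#'       taken as homologous) or `"ref"` (cyclically shift each specimen
#'       to best match the first specimen).}
#'     \item{alpha}{relative-warp exponent (default 0).}
#'     \item{n_axes}{ordination axes (default 3).}
#'     \item{tol, max_iter, allow_reflection}{superimposition settings.}
#'     \item{outdir}{output directory (required).}
#'     \item{quiet}{suppress stage logging (default `FALSE`).}
#'   }
#' @return Object of class `"pipeline_report"` (a list; see fields in the
#'   example), also written to `report.json` in `outdir`.
#' @export
run_full <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(
    list(k = 50L, cyclic_align = "off", alpha = 0, n_axes = 3L,
         tol = 1e-10, max_iter = 100L, allow_reflection = FALSE,
         quiet = FALSE),
    config)
  if (is.null(cfg$outdir)) stop("config$outdir is required")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  log_stage <- function(...) {
    if (!isTRUE(cfg$quiet)) {
      message(sprintf("[%6.2fs] %s", proc.time()[["elapsed"]] - t0,
                      sprintf(...)))
    }
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  seed <- NA_integer_
  records <- stage("input", {
    if (!is.null(cfg$simulate)) {
      sim <- cfg$simulate
      design_path <- sim$design
      sim$design <- NULL
      design <- if (is.null(design_path)) {
        do.call(default_study_design, sim)
      } else do.call(design_from_yaml, c(list(path = design_path), sim))
      seed <- design$seed
      log_stage("simulate: seed %d", design$seed)
      recs <- generate_study(design)
      write_tps(recs, file.path(cfg$outdir, "study.tps"))
      utils::write.csv(study_labels(recs),
                       file.path(cfg$outdir, "labels.csv"),
                       row.names = FALSE)
      if (is.null(config$k)) cfg$k <- design$k_semilandmarks
      recs
    } else if (!is.null(cfg$input)) {
      recs <- read_tps(cfg$input$tps)
      if (!is.null(cfg$input$labels)) {
        recs <- attach_labels(recs, utils::read.csv(cfg$input$labels))
      }
      recs
    } else stop("config needs a 'simulate' or 'input' block")
  })
  log_stage("input: %d specimen records", length(records))

  configs <- stage("resample", {
    lapply(records, function(rec) {
      cv <- normalize_traversal(rec$curves[[1L]])
      resample_equidistant(cv, cfg$k, specimen_id = rec$specimen_id)
    })
  })
  if (identical(cfg$cyclic_align, "ref")) {
    configs <- stage("cyclic_align", {
      ref <- configs[[1L]]
      c(configs[1L], lapply(configs[-1L],
                            function(cc) cyclic_align(cc, ref)$config))
    })
  }
  log_stage("resample: k = %d semilandmarks", cfg$k)

  fit <- stage("gpa", gpa(configs, tol = cfg$tol, max_iter = cfg$max_iter,
                          allow_reflection = cfg$allow_reflection))
  log_stage("gpa: %d iterations, converged = %s", fit$iterations,
            fit$converged)
  tt <- stage("tangent_test", tangent_space_test(fit))
  log_stage("tangent test: uncentred correlation %.6f",
            tt$uncentred_correlation)

  genera <- vapply(records, `[[`, "", "genus")
  consensuses <- stage("consensus",
                       genus_consensus(fit$aligned, genera, tol = cfg$tol,
                                       max_iter = cfg$max_iter,
                                       allow_reflection = cfg$allow_reflection))
  log_stage("consensus: %d genus means", length(consensuses))

  means_fit <- stage("gpa_means",
                     gpa(unname(consensuses), tol = cfg$tol,
                         max_iter = cfg$max_iter,
                         allow_reflection = cfg$allow_reflection))
  rw <- stage("relwarps", relative_warps(means_fit, alpha = cfg$alpha))
  quadrants <- apply(rw$scores[, 1:2, drop = FALSE], 1L, quadrant_of)
  write_scores_csv(rw$scores, file.path(cfg$outdir, "rw_scores.csv"))
  log_stage("relative warps: RW1+RW2 = %.2f%% of variance",
            sum(rw$percent_variance[1:2]))

  dm <- stage("distmat", distance_matrix(consensuses,
                                         allow_reflection = cfg$allow_reflection))
  distmat_path <- file.path(cfg$outdir, "distance_matrix.csv")
  write_distance_csv(dm, distmat_path)

  ord <- stage("pcoa", pcoa(dm, n_axes = min(cfg$n_axes, nrow(dm) - 1L)))
  write_scores_csv(ord$axis_scores, file.path(cfg$outdir, "pcoa_scores.csv"),
                   prefix = "Axis")

  tree <- stage("upgma", upgma(dm))
  newick_path <- file.path(cfg$outdir, "phenogram.nwk")
  write_newick(tree, newick_path)
  coph <- cophenetic_correlation(tree, dm)
  log_stage("upgma: cophenetic correlation %.4f", coph)

  report <- structure(list(
    n_specimens = length(records),
    n_extant = sum(vapply(records, `[[`, "", "status") == "extant"),
    n_genera = length(consensuses),
    k_semilandmarks = cfg$k,
    tangent_test = tt,
    rw_percent_variance = rw$percent_variance,
    genus_scores = rw$scores,
    quadrant_by_genus = quadrants,
    distance_matrix = dm,
    tree = tree,
    cophenetic_correlation = coph,
    pcoa = ord,
    distance_matrix_path = distmat_path,
    newick_path = newick_path,
    config_echo = cfg[setdiff(names(cfg), "quiet")],
    seed = seed,
    software_versions = list(
      R = as.character(getRversion()),
      pronomorph = as.character(utils::packageVersion("pronomorph")))
  ), class = "pipeline_report")
  json <- list(
    n_specimens = report$n_specimens, n_extant = report$n_extant,
    n_genera = report$n_genera, k_semilandmarks = report$k_semilandmarks,
    tangent_uncentred_correlation = tt$uncentred_correlation,
    tangent_slope_through_origin = tt$slope_through_origin,
    rw_percent_variance = as.numeric(rw$percent_variance),
    quadrant_by_genus = as.list(quadrants),
    cophenetic_correlation = coph,
    seed = seed, config = report$config_echo,
    software_versions = report$software_versions)
  jsonlite::write_json(json, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_report: %d specimens (%d extant), ",
                     "%d genera, k = %d>\n"),
              x$n_specimens, x$n_extant, x$n_genera, x$k_semilandmarks))
  cat(sprintf("  tangent-space uncentred correlation: %.6f\n",
              x$tangent_test$uncentred_correlation))
  cat(sprintf("  RW1+RW2 %% variance: %.2f\n",
              sum(x$rw_percent_variance[1:2])))
  cat(sprintf("  cophenetic correlation: %.4f\n",
              x$cophenetic_correlation))
  invisible(x)
}
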