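#!/usr/bin/env Rscript
# Stage 3: genus means, relative warps and ordination.
#
# Specimens are averaged within genera (a Procrustes consensus per genus),
# the 13 genus means are themselves superimposed, and relative warps --
# the principal components of tangent-space shape variation, computed by
# singular-value decomposition of the weight matrix (alpha = 0) -- ordinate
# the genera. Shape change along each warp can be drawn as a thin-plate
# spline deformation of the GLS reference; the warped-grid coordinates for
# the two extreme genera on RW1 are exported for plotting.

suppressPackageStartupMessages(library(pronomorph))

records <- attach_labels(read_tps("results/study.tps"),
                         read.csv("results/labels.csv"))
configs <- lapply(records, function(r)
  resample_equidistant(normalize_traversal(r$curves[[1L]]), 50L,
                       specimen_id = r$specimen_id))
fit <- gpa(configs)
genera <- vapply(records, `[[`, "", "genus")
status <- vapply(records, `[[`, "", "status")

cons <- genus_consensus(fit$aligned, genera)
cat(sprintf("%d genus consensus configurations\n", length(cons)))

means_fit <- gpa(unname(cons))
rw <- relative_warps(means_fit, alpha = 0)
cat(sprintf("RW1 %.2f%%, RW2 %.2f%% -> first two warps %.2f%% of variance\n",
            rw$percent_variance[1L], rw$percent_variance[2L],
            sum(rw$percent_variance[1:2])))

write_scores_csv(rw$scores, "results/rw_scores.csv")
quad <- apply(rw$scores[, 1:2, drop = FALSE], 1L, quadrant_of)
write.csv(data.frame(genus = names(quad),
                     status = status[match(names(quad), genera)],
                     quadrant = quad),
          "results/quadrants.csv", row.names = FALSE)
cat("quadrants of the extant genera:",
    paste(quad[unique(genera[status == "extant"])], collapse = ", "), "\n")

# principal-coordinates ordination of the genus-level Procrustes distances
dm <- distance_matrix(cons)
ord <- pcoa(dm, 3L)
write_scores_csv(ord$axis_scores, "results/pcoa_scores.csv", prefix = "Axis")

# deformation grids: GLS reference -> extreme genera on RW1
extremes <- rownames(rw$scores)[c(which.min(rw$scores[, 1L]),
                                  which.max(rw$scores[, 1L]))]
grids <- do.call(rbind, lapply(extremes, function(g) {
  gg <- deformation_grid(means_fit$consensus, cons[[g]], n_grid = 20L)
  gg$genus <- g
  gg
}))
write.csv(grids, "results/deformation_grids.csv", row.names = FALSE)
cat("wrote results/rw_scores.csv, quadrants.csv, pcoa_scores.csv,",
    "deformation_grids.csv\n")
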