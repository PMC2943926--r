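#!/usr/bin/env Rscript
# Stage 4: Procrustes distance matrix and UPGMA phenogram.
#
# Partial Procrustes distances between the 13 genus consensus shapes are
# clustered by UPGMA (size-weighted average linkage, heights = d/2); the
# phenogram summarizes overall phenetic similarity of pronotum shape. The
# cophenetic correlation measures how faithfully the tree represents the
# distance matrix, and the extant genera are checked for forming a clade.

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
dm <- distance_matrix(cons)
write_distance_csv(dm, "results/distance_matrix.csv")

tree <- upgma(dm)
write_newick(tree, "results/phenogram.nwk")
cat(sprintf("cophenetic correlation: %.4f\n",
            cophenetic_correlation(tree, dm)))

extant <- unique(genera[status == "extant"])
coph <- cophenetic_matrix(tree)
inside <- rownames(coph) %in% extant
clade <- max(coph[inside, inside]) < min(coph[inside, !inside])
cat(sprintf("the %d extant genera form a clade: %s\n", length(extant),
            clade))
cat("wrote results/distance_matrix.csv and results/phenogram.nwk\n")
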