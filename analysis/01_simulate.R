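#!/usr/bin/env Rscript
# Stage 1: simulate the study material.
#
# The real pronotum outlines were digitized from published figures and are
# not deposited anywhere, so the analysis runs on synthetic outlines drawn
# from the packaged 13-genus study design: 8 monotypic fossil genera and 5
# extant genera holding 10/5/3/1/1 species (28 outlines, 20 extant), each
# a Fourier-perturbed closed curve with genus-level mean shape,
# species-level coefficient noise, digitizing jitter and an arbitrary
# rotation/translation/scale per specimen.

suppressPackageStartupMessages(library(pronomorph))
dir.create("results", showWarnings = FALSE)

design <- default_study_design(seed = 1L)
records <- generate_study(design)
labels <- study_labels(records)

write_tps(records, "results/study.tps")
write.csv(labels, "results/labels.csv", row.names = FALSE)

cat(sprintf("simulated %d specimen outlines in %d genera (%d extant, %d fossil)\n",
            length(records), length(unique(labels$genus)),
            sum(labels$status == "extant"), sum(labels$status == "fossil")))
print(table(labels$genus))
cat("wrote results/study.tps and results/labels.csv\n")
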