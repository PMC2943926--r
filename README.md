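# pronomorph

Outline-based geometric morphometrics of the insect pronotum, built for
comparing pronotum shape across the 13 extant and fossil genera of
Grylloblattodea (ice crawlers). The pronotum — the dorsal plate of the
first thoracic segment — is one of the few shape characters preserved in
both living species and Permian–Jurassic fossils, so overall phenetic
similarity of pronotum outlines can be summarized across the whole order.

The package implements the complete analysis chain:

- **TPS digitizing I/O** — reader/writer for the `LM=` / `CURVES=` /
  `POINTS=` / `ID=` / `IMAGE=` / `SCALE=` record format of the tps
  digitizing tools, plus CSV score tables, distance matrices and Newick
  trees.
- **Semilandmarks** — a closed outline is oriented counter-clockwise and
  resampled to *k* arc-length-equidistant semilandmarks (study default
  *k* = 50).
- **Superimposition** — generalized least-squares (GLS) Procrustes
  analysis: every configuration is centered, scaled to unit centroid size
  and rotated to an iteratively re-estimated consensus. Partial Procrustes
  distance is `d = sqrt(sum_i |x_i - y_i|^2)` between optimally rotated
  unit-size configurations; the geodesic distance on Kendall's shape
  space is `rho = 2 asin(d/2)`.
- **Tangent-space diagnostic** — per specimen, the geodesic distance
  `rho` to the consensus and the Euclidean norm `Y` of its tangent-plane
  projection; the uncentred correlation
  `sum(rho Y) / sqrt(sum(rho^2) sum(Y^2))` near 1 certifies that linear
  statistics in the tangent plane approximate shape space.
- **Relative warps** — principal components of shape variation by
  singular-value decomposition of the column-centered weight matrix of
  tangent residuals (exponent alpha = 0 by default; alpha != 0 reweights
  partial warps by bending-energy eigenvalues). Thin-plate splines
  (`U(r) = r^2 log r^2`) render shape change as deformation grids of the
  GLS reference.
- **Phenetics** — partial Procrustes distances between the 13 genus
  consensus shapes, UPGMA clustering (size-weighted average linkage,
  heights d/2), Newick export, cophenetic correlation, and
  principal-coordinates ordination of the distance matrix.
- **Synthetic outlines** — the raw outlines were digitized from published
  figures and are not deposited, so a seeded generator emulates the study
  design: 28 pronotum-like Fourier outlines in 13 genera (8 monotypic
  fossil genera; extant genera with 10/5/3/1/1 species), with genus mean
  shapes, species-level coefficient noise, vertex jitter and nuisance
  rotation/translation/scale.

## Worked example

The numbered scripts under `analysis/` run the whole study:

```sh
Rscript analysis/01_simulate.R        # 28 outlines, 13 genera -> results/study.tps
Rscript analysis/02_superimpose.R     # semilandmarks + GPA + tangent test
Rscript analysis/03_relative_warps.R  # genus means, relative warps, PCoA
Rscript analysis/04_phenetics.R       # distance matrix, UPGMA phenogram
```

which prints, at the packaged design and seed 1:

```
GPA converged in 5 iterations
tangent-space uncentred correlation: 0.999997 (slope 0.995955)
RW1 79.87%, RW2 11.20% -> first two warps 91.08% of variance
quadrants of the extant genera: I, I, I, I, I
cophenetic correlation: 0.8953
the 5 extant genera form a clade: TRUE
```

The tangent correlation of 0.999997 says the shape variation is small
enough for tangent-space statistics; the first two relative warps carry
91% of among-genus variation; the five extant genera fall in one quadrant
of the RW1/RW2 plane and form a clade of the UPGMA phenogram — the
synthetic design plants the extant genera as one compact shape family,
and the pipeline recovers exactly that structure.

The same run is available in one call:

```r
library(pronomorph)
report <- run_full(list(simulate = list(seed = 1L), outdir = "results"))
report
#> <pipeline_report: 28 specimens (20 extant), 13 genera, k = 50>
#>   tangent-space uncentred correlation: 0.999997
#>   RW1+RW2 % variance: 91.08
#>   cophenetic correlation: 0.8953
```

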