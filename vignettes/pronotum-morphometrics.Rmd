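---
title: "Outline morphometrics of grylloblattodean pronota: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outline morphometrics of grylloblattodean pronota: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pronomorph)
```

## The problem

Grylloblattodea comprises five extant wingless genera and a much more
diverse fossil assemblage. Few morphological characters bridge the two:
the pronotum outline is one of them. The question this package serves is
phenetic: how similar are pronotum shapes across the 13 genera (8 fossil,
5 extant), and do the modern genera form a coherent shape family? The
answer is computed as an ordination of genus mean shapes (relative warps)
and a UPGMA phenogram of Procrustes distances.

Because the original outlines were digitized from published photographs
and were never deposited, the package carries a synthetic outline
generator that reproduces the *design* of the study — taxon composition,
nuisance transforms, noise structure — so every statistical step can be
exercised and tested end to end. Conclusions about the real animals
cannot be regenerated from synthetic data; what can be verified is that
the machinery recovers known, planted structure.

## Shape model and procedure

**Semilandmarks.** Each specimen is a closed outline (an ordered polygon,
first vertex not repeated). It is oriented counter-clockwise by the
signed-area test and resampled to $k$ points equally spaced in arc
length, measured from the digitized start vertex; $k = 50$ is the study
convention. Semilandmarks are treated as fixed landmarks afterwards — no
sliding by bending energy or perpendicular projection — because the
analysis chain being reproduced used plain equidistant resampling.
Start-point homology is the digitizer's responsibility (conventionally
the anterior midline point); `cyclic_align()` is available when that
convention cannot be trusted, choosing per specimen the cyclic shift
minimizing the Procrustes distance to a reference.

**Superimposition.** Configurations are centered, scaled to unit
centroid size and rotated to the consensus by generalized least squares,
with the consensus re-estimated as the renormalized mean until it moves
less than `tol` (default `1e-10`, partial Procrustes distance) or
`max_iter` (100) is reached; the first configuration seeds the consensus.
Full renormalization every iteration (partial Procrustes) matches the
GLS convention of the tps programs, rather than optimal-scaling variants.
Reflections are excluded by default (rotation determinant +1): dorsal
pronotum outlines have fixed handedness, though `allow_reflection`
exists for mirrored figures. GPA results are invariant to input order
and to arbitrary similarity transforms of the inputs, up to the global
orientation of the consensus; the test suite asserts both.

**Distances.** Between-shape dissimilarity is the partial Procrustes
distance $d$ (root-sum-of-squares after optimal superimposition of
unit-size shapes). Where an angle is required — the tangent-space
diagnostic — the geodesic distance $\rho = 2\arcsin(d/2)$ in radians is
used. Both are genuine metrics (quotient metrics of the isometric
rotation action on the preshape sphere), and the triangle inequality is
property-tested on random triples.

**Tangent-space diagnostic.** Linear multivariate statistics require the
data to sit in the tangent plane to shape space at the consensus. Each
aligned shape (a unit vector $x$) is projected as
$x_t = x - z (z \cdot x)$, $z$ the consensus unit vector; the diagnostic
regresses the tangent norm $Y = \lVert x_t \rVert$ on $\rho$ and reports
the uncentred correlation. At exact projection $Y = \sin\rho$, so
$|Y - \rho| \le \rho^3/6$ and the correlation approaches 1 as variation
shrinks. Both the through-origin slope (primary, matching the
diagnostic's plot through the origin) and the free-intercept slope are
reported, since the classical tool's regression variant is not
documented.

**Genus means and relative warps.** Specimens are averaged within genera
(a GPA consensus per genus; a monotypic genus contributes its single
normalized shape), and the 13 genus means are superimposed again before
any cross-genus analysis — the average-then-compare hierarchy of the
original tool chain. Relative warps are the principal components of the
tangent residuals of the means: the $n \times 2k$ weight matrix is
column-centered and decomposed by SVD; squared singular values normalized
to 100 give percent variance; at most $\min(n-1,\,2k-4)$ warps are
nonzero (centering plus the four similarity constraints). With
$\alpha = 0$ (default, and the only value under which "SVD of the weight
matrix" coincides with ordinary shape PCA) residuals enter unweighted,
uniform and non-uniform variation together. For $\alpha \neq 0$ the
non-affine part of each residual is rescaled in the principal-warp basis
of the consensus bending-energy matrix by $\lambda^{-\alpha/2}$, leaving
the affine part unscaled. SVD sign ambiguity is fixed by making the
largest-magnitude loading of each warp vector positive.

**Thin-plate splines.** The bending-energy matrix is the upper-left
$k \times k$ block of $L^{-1}$, with
$L = \begin{bmatrix} K & Q \\ Q^\top & 0\end{bmatrix}$,
$K_{ij} = U(r_{ij})$, $U(r) = r^2 \log r^2$, $Q = [\,1\;x\;y\,]$. It is
symmetric positive-semidefinite with exactly three zero eigenvalues
(affine maps); the warp solving the same bordered system interpolates
every landmark exactly, and deformation grids are warped regular grids
of the GLS reference at a stated magnification (default $\times 1$).

**Ordination of the distance matrix.** The classical workflow describes
ordinating the genus means on canonical axes derived from the Procrustes
distance matrix, which is internally contradictory — canonical variates
need within-group covariance, which a design of 13 single mean shapes
cannot supply. The faithful computable reading is principal-coordinates
analysis (classical MDS) of the distance matrix, and that is what
`pcoa()` implements (via `stats::cmdscale`); the discrepancy is
documented here rather than resolved. Three axes are extracted by
default; axes with negative eigenvalues are reported and dropped.

**Phenetics.** `upgma()` implements size-weighted average linkage
(UPGMA proper, per the method's expanded name, not WPGMA), merge heights
$d/2$ so root-to-leaf paths equal half the cophenetic distance, and
deterministic tie-breaking (the pair containing the smallest leaf index,
children ordered likewise). The classical implementation's tie rule is
undocumented, so this convention is stated rather than guessed.
`cophenetic_correlation()` is the standard companion diagnostic. Newick
export writes height differences as branch lengths; an independent
Newick parser is used in the tests to confirm topology and path lengths.

## The synthetic study design

`default_study_design()` mirrors the real taxon table exactly: 8
monotypic fossil genera, and extant *Galloisiana* (10 species),
*Grylloblatta* (5), *Grylloblattella* (3), *Grylloblattina* (1),
*Namkungia* (1) — 28 outlines, 20 extant. Each outline is a truncated
Fourier perturbation of a circle,
$r(\theta) = r_0(1 + \sum_{h=1}^{4} a_h \cos h\theta + b_h \sin h\theta)$,
a compact family that covers rounded-quadrate pronotum-like shapes,
gives analytic symmetry cases for tests, and keeps genus means
interpretable as 8 coefficients. Defaults, chosen once as plausible for
digitized outlines of this kind:

| parameter | default | meaning |
|---|---|---|
| `within_genus_sd` | 0.008 | per-coefficient SD of species about the genus mean (shape-scale Procrustes scatter roughly 0.016) |
| `landmark_jitter_sd` | 0.002 | per-vertex digitizing jitter, units of $r_0$ |
| `nuisance` | on | rotation $U(0,2\pi)$, scale log-uniform on $(0.5, 2)$, translation $U(-10,10)^2$ |
| `n_vertices` | 200 | digitized polygon density |
| `k_semilandmarks` | 50 | study convention |

The five extant genus means are placed in one compact region of
coefficient space and the fossil means dispersed around it, emulating
the qualitative structure reported for the real data (modern genera
mutually similar, fossils heterogeneous). One integer seed drives
everything; each record uses a counter-derived substream so its outline
does not depend on generation order, and the emitted TPS file is
byte-reproducible.

What the generator does *not* emulate: digitizing bias along the outline,
correlated (non-isotropic) landmark error, allometry, and any real
phylogenetic signal. Passing tests therefore demonstrate correctness of
the machinery and recoverability of planted structure at realistic noise
— not properties of real grylloblattodean pronota.

**Planted-recovery conditions.** The recovery tests construct designs in
which the planted effect is at least five times the relevant scatter
(measured as Procrustes distances): extant genus means pulled halfway
toward their family centroid and fossil means pushed 1.7× away gives an
extant-family separation ≈ 8.7× the within-family scatter; a
within-genus SD of 0.001 gives genus-mean separations ≈ 6.3× the
within-genus scatter. Under those conditions the extant clade and the
per-genus clades are each required in ≥ 95 of 100 seeded replicates.

## Numerical choices and degenerate inputs

- GPA tolerance `1e-10` on consensus movement, cap 100 iterations; the
  study-scale problem converges in about 5. A final rotation pass leaves
  every aligned shape optimally rotated to the returned consensus, so
  tangent projections satisfy $Y = \sin\rho$ to machine precision.
- Zero-length curves, coincident landmarks (singular TPS kernel),
  all-coincident configurations, collinear closed curves (zero signed
  area), empty genus labels, and an all-identical specimen set for the
  tangent diagnostic are rejected with specific errors rather than
  propagating NaNs.
- `SCALE=` factors are applied at read time (centroid sizes become
  physically meaningful; shape results are unaffected); written TPS
  files carry the already-scaled coordinates at full precision, so a
  write/read cycle is the identity.
- Image-origin y-axes can be flipped with `read_tps(negate_y = TRUE)`;
  coordinates are otherwise taken as-is, since superimposition with
  reflections disabled makes consistency, not orientation, the
  requirement.
- Problem sizes in the shipped tests and drivers: 28 specimens × 50
  semilandmarks for the study pipeline; 100 replicates for each recovery
  property (at $k = 50$ for the family condition, $k = 30$ for the
  per-genus condition); the whole suite runs in well under a minute.

## Known limitations

- Sliding semilandmarks, allometry regression, CVA proper, resistant-fit
  superimposition, 3-D shapes and bootstrap support are out of scope.
- The headline statistics of the real pronotum data (its near-unity
  tangent correlation and the share of variance on the first two
  relative warps) were computed from undeposited digitized outlines and
  cannot be reproduced; the synthetic design yields numbers of the same
  character — a tangent correlation within about 1e-5 of 1 and roughly
  80% of variance on RW1 at the default design — but they describe the
  synthetic material only.
- UPGMA tie-breaking and the tangent-test regression variant follow
  stated conventions where the classical tools are undocumented.
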