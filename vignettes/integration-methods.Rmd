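---
title: "Cross-modal integration of smFISH and scRNA-seq: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal integration of smFISH and scRNA-seq: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikemap)
```

## The problem

Targeted spatial transcriptomics (combinatorial smFISH, e.g. Molecular
Cartography) counts individual transcripts of a curated ~100-gene panel at
sub-cellular resolution in tissue sections, while droplet scRNA-seq measures
the whole transcriptome of dissociated cells with no spatial information.
In developing cereal spikes — where meristem identities turn over within a
few hundred micrometres — neither modality alone answers where a given
transcriptome state lives. `spikemap` implements the two transfer
directions that connect them, plus the statistics used around them:
expression imputation into spatially anchored cells, and projection of
spatial cluster labels onto single cells.

## Cross-modal matching

Both matrices are reduced to the shared panel and normalized to counts per
million (CPM). CPM without a log transform is the default similarity layer;
cosine similarity is scale-free, so per-cell depth differences cancel and
what remains is the direction of the panel profile. The log layer is
exposed (`layer` argument / `lognormalize()`) for sensitivity analyses.

For query cell $q$ and reference cell $r$,

$$ s(q, r) = \frac{q \cdot r}{\lVert q \rVert\, \lVert r \rVert} \in [0, 1] $$

for nonnegative expression vectors. The k = 5 nearest references are found
exactly — all pairwise similarities are computed in blocks; there is no
approximate index. At the scale this design targets (10³–10⁵ cells,
≤ 100 panel genes) the exact search costs seconds and is testable against a
brute-force oracle, which the test suite does on randomized instances. Ties
are broken by lexicographic reference id so results are reproducible to the
bit. Cells that are all-zero over the panel have undefined cosine direction;
they are excluded and reported, never silently dropped.

### Imputation

Imputed expression is the similarity-weighted average
$\hat{x}(q, g) = \sum_i s_i x(r_i, g) / \sum_i s_i$. Weights are normalized
to sum to one, so every imputed value is a convex combination of neighbour
values — an invariant the tests assert. The unnormalized variant (plain
weighted sum) is kept as a sensitivity check only. Stages are matched and
imputed separately, then merged over the union of cells and genes; a gene
imputed in only one stage is *missing* (NA), not zero, for the other
stage's cells, so downstream averages are not biased toward zero.

### Label projection and the contribution matrix

In the reverse direction each scRNA-seq cell queries its 5 nearest smFISH
cells. Neighbours with $s \le 0.3$ are removed first; the cell adopts the
most frequent remaining spatial-cluster label. If every remaining label is
unique there is no common cluster among the neighbours and the cell gets no
projection. For frequency ties (e.g. 2–2–1) the label with the larger
summed similarity wins; an exact tie also yields no projection. The 0.3
filter is applied to every neighbour, not only the first — the strictest
uniform reading — and the tie rules are deterministic by construction.

The contribution matrix counts projected cells per (spatial cluster,
scRNA cluster) pair and divides each row by the spatial cluster's total
cell count, correcting for cluster-size differences. Note the fractions
are counts of *scRNA* cells over *smFISH* cluster sizes: when the scRNA
modality has more cells per cluster the fractions exceed 1. They are
comparable within and across rows, which is what the row-argmax pairing
analysis uses; they are not probabilities.

## Cluster-level statistics

Pseudobulk profiles are arithmetic means of normalized expression per
cluster. The informative-gene filter keeps genes with coefficient of
variation (sample sd over mean of cluster means) strictly above 0.5 and a
total sum across clusters inside the closed interval [0.1, 20]. The CV
bound removes flat genes; the sum bounds remove genes dominated by zeros or
by extreme expression. Sample sd (n − 1) is used because n is the number of
clusters, typically ~20; a population-sd option is exposed. Pearson
matrices are computed within a study or rectangularly across studies; for
polyploid wheat cross-study comparisons the profile carrying individual
homeologs is first collapsed by summing group members, with members absent
from a panel contributing zero (panels from different studies rarely
measure all subgenome copies). Hierarchical ordering of correlation
matrices (Euclidean distance, complete linkage) is provided purely for
display.

## Markers, co-expression, protoplasting artifacts

Markers use a one-vs-rest two-sided Wilcoxon rank-sum test with the normal
approximation and tie correction (no continuity correction), vectorized
over genes; `stats::wilcox.test` is the independent oracle in the tests.
pct.1/pct.2 are the fractions of nonzero cells inside/outside the cluster;
log2FC de-logs the group means and adds the pseudocount at the group level,
$\log_2\frac{\mathrm{mean}(e^{x_{in}}-1) + 1}{\mathrm{mean}(e^{x_{out}}-1) + 1}$.
Adjustment is Bonferroni over all genes × clusters tests (BH by flag).
Clusters with fewer than 3 cells yield records with missing p-values rather
than errors. The strict filter (pct.1 > 0.10, pct.2 < 0.10,
adj. P < 0.001, log2FC > 1) is the default marker definition; the relaxed
filter (log2FC > 1, no pct.1 bound, pct.2 < 0.2, adj. P < 0.01) exists for
clusters with few enriched genes. All inequalities are strict, and both
predicates are verified on an exhaustive grid of boundary values.

The co-expression screen correlates a target gene with every other detected
gene (nonzero in ≥ 3 cells) across all cells and selects genes with
$r > \bar{r} + 4\,\mathrm{sd}(r)$. The target itself and constant genes are
excluded from the distribution, so the trivial $r = 1$ self-term cannot
inflate the threshold; homeologs of the target stay in and are expected top
hits. Protoplasting scoring reports, per cluster, the percentage of markers
overlapping a stress-gene list and the percentage absent from bulk RNA-seq
of intact tissue, plus the cross-cluster Pearson correlation of the two
percentages — two independent views of the same artifact that should agree
when a cluster is stress-driven.

## Spatial statistics

Spot counting uses an even-odd point-in-polygon rule that is boundary
inclusive: a spot exactly on an edge or vertex belongs to the region.
Boundary hits are decided with exact cross-product arithmetic, which keeps
counting deterministic and makes densities additive over disjoint polygons.
Densities are spots per 100 μm² with the shoelace polygon area.

Between-stage comparisons first average sections from the same spike
(technical replicates), then run a two-sided Welch t-test on per-spike
densities. Welch is the package's choice for small unbalanced designs
(4 vs 2 spikes) with no variance-equality assumption. A stage with fewer
than 2 spikes yields a missing p-value but the fold change is still
reported; a zero-mean denominator yields an infinite fold change with a
flag, never an exception.

Region assignment fits a one-way layout per gene over the three spike
regions and applies Tukey's HSD; the winner is the region with the largest
mean provided its contrast against the runner-up is significant at α = 0.05
(a stricter all-contrasts rule is available). Degenerate tables with zero
within-region variance but unequal means are assigned with p reported as 0
and flagged. Region enrichment per cluster is a chi-square goodness-of-fit
of winner counts against uniform (df = regions − 1), with a small-count
flag below 5 assigned genes.

## The synthetic-data generator

The generator defines one ground-truth world observed through both
modalities: a clusters × genes mean matrix $M$, balanced cluster
assignments, and negative-binomial counts with
$\mathrm{Var} = \mu + \alpha \mu^2$ ($\alpha = 0$ degenerates to Poisson,
which the tests exploit as a closed-form limit). Defaults: 6 clusters,
1500 spatial × 3000 sc cells, a 95-gene panel inside 2000 genes,
$\alpha = 0.3$ (typical droplet-data overdispersion), per-cell library
factors lognormal with log-sd 0.3 and unit mean (so expected counts equal
$M$ and CPM normalization is non-trivial), per-(cluster, gene) log2 fold
effects N(0, 1.5), and base means lognormal(log 3, 0.8) for panel genes
versus lognormal(0, 1.2) for the rest — a curated marker panel is selected
for well-expressed, dynamically varying genes, and the panel mimics that.

Spatial cells are laid out in one vertical strip of the square domain per
cluster with uniform jitter: same-cluster cells are contiguous, which is
the property the integration tests need; no realistic tissue morphology is
attempted. Spot tables place exactly count-many spots uniformly in each
cell's disc, so spot-level and cell-level quantification agree by
construction.

Planted structure carries its own parameters: co-expressed pairs share a
per-cell lognormal latent factor whose log has correlation ρ between the
two genes, with a fixed plant base mean (3 counts/cell by default in the
shipped analyses) because a pair planted in an effectively unexpressed gene
would be unobservable; stress genes get a flat base profile and a
multiplier only in designated clusters of the sc modality, emulating
protoplasting induction that the intact-tissue spatial modality never sees.

What passing tests show — and don't. The generator reproduces the
statistical skeleton the method relies on (cluster-structured means shared
across modalities, overdispersed counts, library-size variation, spatial
contiguity). It omits batch effects, doublets, segmentation errors,
spot-decoding noise and realistic morphology, so recovery rates on
synthetic data (imputation correlation ≈ 0.998, projection accuracy
≈ 0.999 at the default scale) are upper bounds on real-data performance,
not estimates of it.

## Calibration analyses and problem sizes

The shipped acceptance analysis uses the default 6-cluster paired study for
integration recovery; a single-cluster, 502-gene, 3000-cell dataset for the
co-expression screen calibration (with clusters present, cluster-level
co-variation is genuine co-expression, so a proper null requires removing
it — non-planted genes are then truly uncorrelated and any selection is a
false positive); a 6-cluster study with eight stress genes split between
two designated clusters for protoplasting scoring (each gene induced in one
cluster — a gene induced in two clusters appears in each cluster's
out-group and is no longer a clean cluster marker); and 2000 simulated
uniform count triplets for chi-square type-I calibration. These sizes keep
every analysis within desk-scale minutes while leaving comfortable margins
on the tested properties.

## Numerical and degenerate-input choices

Similarities are clamped at 1 against rounding overshoot; kNN ties break
lexicographically; QC intervals are closed (a cell exactly at a bound is
retained); CPM requires positive cell totals and errors on zero-total
cells; homeolog groups reject duplicate members; readers reject dimension
mismatches, duplicate ids and malformed rings instead of coercing; writers
round-trip integers bit-exactly and reals to full double precision. All
randomness flows through explicit seeds; two runs with the same
configuration and seed are identical to the bit.

## Known limitations

Imputation inherits the biases of the reference: a transcriptome state
absent from the scRNA-seq data cannot be imputed into space, and panel
genes dominated by a single homeolog may match across subgenomes. The
projection's 0.3 cosine floor is a heuristic inherited from the original
design; values near the floor deserve sensitivity checks via the exposed
parameter. The even-odd boundary-inclusive rule double-counts a spot lying
exactly on the shared edge of two adjacent regions. Welch on 2 spikes per
stage has little power; the p-value is reported, not optimized.
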