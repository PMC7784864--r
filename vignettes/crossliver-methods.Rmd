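---
title: "Methods: cross-species fetal-liver single-cell analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species fetal-liver single-cell analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossliver)
```

This vignette explains the models and procedures the package implements,
the assumptions behind them, the parameters that matter, and the design
decisions taken where the underlying methodology left choices open. The
package targets comparative droplet scRNA-seq of human and mouse fetal
liver: 13 major cell types organized in four lineage families, a
hepatoblast-to-hepatocyte differentiation continuum with a cholangiocyte
branch, and cross-species conservation analyses built on one-to-one
orthologues.

## Normalization, QC and variable genes

UMI counts are depth-normalized per cell to a common total and
ln-transformed with a pseudo-count of one: `lnTP10K` (scale factor 10,000)
for droplet data and `lnTP0.1M` (100,000) for deep plate-based data.
`normalize_log()` guarantees that the back-transform of every cell sums to
the scale factor, a conservation property the tests verify. QC removes
cells detecting fewer genes than a threshold (strictly below; the
threshold itself survives). `find_variable_genes()` implements the
mean/dispersion method: per-gene dispersion (variance over mean of the
back-transformed values) is z-scored within equal-width bins of ln-scale
mean expression. Defaults are 20 bins, z ≥ 1, and ln-mean bounds
[0.0125, 8]: the classical upper bound of 3 presumes a genome-wide
(~20,000 gene) matrix, and on the compact gene panels this package
typically processes per-gene means are proportionally larger, so a cap of
3 would discard genuinely variable highly expressed genes. Scaling uses
the sample SD (n − 1), zeroes constant genes, and clips at ±10.

## Doublet detection

Artificial doublets emulate the transcriptome of two co-encapsulated
cells: 10% of cells are sampled twice without replacement, and the two
subsets are merged pairwise by *summing* counts — a sum, not a mean,
because a droplet containing two cells contains the union of their
molecules. After joint normalization and PCA of the union, the doublet
index of each real cell is the proportion of artificial doublets among
its k nearest neighbours, with k equal to 1% of the union size (the index
is computed in the union's PC space, so the neighbourhood is defined on
the union). Cells at or above the 90th percentile of indices are putative
doublets; because the index is quantized in units of 1/k, ties at the
threshold are flagged inclusively and the putative set can exceed 10%.
Doublet-related genes (Wilcoxon, Bonferroni-adjusted p < 0.01,
|ln-FC| > 0.25) define a re-clustering space in which clusters with a
putative fraction above 0.5 (configurable; the underlying criterion
"high putative percentage" is not quantified anywhere authoritative)
become definitive doublets. A variant for erythrocyte-derived doublets
finds the principal component with maximal aggregate hemoglobin-gene
loading, clusters cells on that component's top-loading genes, and
removes hemoglobin-high clusters — only when the per-cluster hemoglobin
scores actually separate (range above 1 ln unit), so uniform hemoglobin
expression removes nothing.

The detection floor of the method is intrinsic: a doublet formed from two
cells of the same type is, after depth normalization, indistinguishable
from a singlet of that type, so ranking performance saturates below 1.
At desk scale (~2,000 cells) the expected index of such doublets is the
null value N_art/(N_union − 1).

## Clustering and lineage families

`snn_cluster()` follows the standard graph pipeline — variable genes,
scaled PCA (20 PCs), kNN graph (k = 30), shared-nearest-neighbour Jaccard
re-weighting with 1/15 pruning, Louvain modularity at resolution 0.8 —
then applies a marker-support check: modularity optimization reports
communities even in structureless data, so any two clusters whose
strongest separating gene has |ln-FC| below 1 are merged. This keeps the
negative control honest (no planted signal gives one cluster) without
touching genuinely separated populations, whose planted markers differ by
ln-FC 3. Iterative subclustering re-runs the full pipeline inside each
major population with namespaced labels. Batch correction is a linear
per-batch centering of the embedding (an adapter point for external
correctors; panorama-style stitching is deliberately out of scope).

Cross-species similarity of cell types is the Pearson correlation of
per-type mean expression over one-to-one orthologues. Each gene's profile
is standardized across types within its species first: baseline
expression is nearly identical between any two types and would otherwise
dominate the correlation; the comparison is meant to capture *relative*
expression patterns, and it should be computed on informative genes
(e.g. the consensus DE union) for the same reason. Families are the
average-linkage clusters of 1 − correlation over both species' types
jointly, cut at the requested family count (4 by default, matching the
biology; the cut count is exposed).

## Consensus differential expression

Unbalanced population sizes bias one-vs-rest testing, so each repeat
draws a balanced subset (100 cells per population; smaller populations
are taken whole with a warning), optionally smooths dropout zeros by
kNN-mean imputation (off by default; its effect is an explicit flag, not
silent), and tests every population one-vs-rest with a two-sided Wilcoxon
rank-sum: tie-corrected, continuity-corrected normal approximation,
exact null distribution when both groups have at most 10 untied
observations — documented precisely because comparisons at p ≈ 10⁻²⁰
must be numerically stable. Genes with p < 10⁻²⁰ are recorded per repeat,
and the consensus set is the intersection over all 50 repeats: a gene
significant in 49 of 50 repeats is excluded. The per-repeat threshold is
applied to raw p-values (whether the original procedure adjusted before
the 10⁻²⁰ cut is unstated; at that stringency the distinction is almost
immaterial and the choice is recorded here).

## Co-expression networks and species specificity

Networks are unsigned: adjacency |cor|^β with β = 6 (the conventional
unsigned default; the original soft power is unstated, and every output
records the β used), topological overlap
TOM᎐ij = (Σᵤ a᎐iu a᎐uj + a᎐ij)/(min(kᵢ, kⱼ) + 1 − a᎐ij), diagonal fixed
at 1, and centrality defined as weighted degree kᵢ = Σ a᎐iu. Modules are
average-linkage clusters of 1 − TOM. A fixed absolute cut height cannot
work across datasets: at β = 6 the absolute TOM scale varies by orders of
magnitude with the overall correlation level. The default cut is
therefore data-driven — the 95th percentile of the dendrogram's own merge
heights, which separates the few high inter-module merges from the bulk
of within-module merges on any scale — with `cut_height` available as an
explicit override and modules below 10 genes left unassigned (module
"0"), mirroring the grey-module convention. Network conservation between
species is the Pearson correlation of orthologue-paired centralities.

The eigengene of a gene set is the first principal component of its
per-gene standardized expression, scaled to unit variance and
sign-oriented to correlate positively with the set's mean expression.
Genes are called species-specific when their correlation with one
species' eigengene exceeds 0.5 *and* exceeds the other species'
correlation by more than 0.5 — both thresholds are fixed by the method
being reproduced. These correlations should be computed on the balanced,
dropout-smoothed matrices; at droplet depth the per-gene correlation of
even a true module member hovers near the 0.5 threshold without
smoothing.

## Trajectory and heterogeneity

Because hepatoblasts/hepatocytes outnumber cholangiocytes by an order of
magnitude, trajectory PCA samples the majority lineage per stage (250 for
human, 80 for mouse — proportional to each species' cholangiocyte pool)
and keeps every cholangiocyte. Variable genes are found on the
concatenation with a deliberately permissive dispersion cut (z ≥ 0.25):
genes that change gradually and monotonically along a continuum have
modest dispersion compared to binary (on/off) programs, and with the
standard z ≥ 1 cut the maturation axis loses the gene-count contest
against branch programs and no longer dominates PC1. Cell-cycle-related
genes (|r| > 0.3 with either cycle score) are removed before PCA. The
PCA stores per-gene center and scale so external cells can be projected
exactly: projection of a training cell reproduces its stored score to
1e-8, missing genes contribute zero after scaling (the training mean — a
conservative choice), and projection is linear.

Cell-cycle scoring re-implements module scoring with expression-matched
controls: all genes are binned into 10 expression-magnitude bins
(n.bin = 10), each signature gene draws up to 100 control genes from its
bin, and the score is mean(signature) − mean(controls); a cell is S or
G2M if that score is the larger of the two and positive, G1 otherwise.
The proliferative fraction of a stage is its proportion of S/G2M cells.

Stage-switch detection clusters per-stage mean profiles (average linkage,
correlation distance) and maps the dendrogram's top bipartition onto
temporal order; a non-contiguous bipartition is reported as such, never
silently converted into a boundary. The split depth, 1 − h₂/h₁ over the
two highest merge heights, gates confidence at 0.25: stage-exchangeable
data produce depths near 0.05, a planted transition near 0.5. A known
limitation is documented rather than hidden: a fast *smooth* drift also
produces a deep contiguous split, so stage-profile clustering alone
cannot distinguish an abrupt switch from steep gradual change — the
boundary is trustworthy when the underlying biology is known to be
transition-like.

Cross-species combination excludes species-specific genes via the
orthologue map, z-scales genes within each species separately (removing
species-level offsets so that a relabeled copy of one species shows no
species axis), and runs PCA on the union of the two species'
variable-gene sets. Bimodal group classification scores cells by
PC-related genes (positive-sign mean minus negative-sign mean) and splits
the score with 2-means; bimodality is accepted only when a two-component
Gaussian mixture beats a single Gaussian by more than 10 BIC units. A
silhouette gate was considered and rejected: splitting a unimodal 1-D
distribution at its centre already yields mean silhouettes around 0.5, so
silhouette cannot reject unimodality. Group labels low/high follow score
order. The diffusion map uses a Gaussian kernel on Euclidean PC distances
(bandwidth: median distance to the 15th neighbour), density
normalization, and the leading non-trivial right eigenvectors of the
row-stochastic transition matrix.

## The synthetic data generator

The generator is first-class, tested code, and its defaults *are* the
study conditions the package is validated against: 13 cell types in 4
families (2 endoderm, 4 erythroid, 3 non-erythroid hematopoietic, 4
mesodermal non-hematopoietic), 20 markers per type at ln-FC 3,
family-shared programs at half the marker effect (tying the family effect
to the marker effect makes `marker_log_fc = 0` a true negative control),
negative-binomial counts (dispersion 0.3) with gamma library sizes
(mean 2,000, shape 10), two batches with log-normal shifts (SD 0.15), a
rare early-stage hepatoblast subpopulation at 8% (human) / 6% (mouse)
expressing a mesenchymal program, and 100 paired orthologues per species
planted with species-specific expression patterns (a type program active
in one species only). The trajectory generator places cells on a latent
axis increasing with stage, with a decreasing program A and increasing
program B (effects centred at ±half the contrast so planted genes do not
migrate out of the realistic mean range), a branch-only program C, a
30-gene block stepping by ln-FC 1.5 exactly between stages 4 and 5 (the
mouse timeline position of the reported transition), S/G2M signatures of
40 genes each whose baseline sits below the transcriptome bulk (cycle
genes are phase-specific markers, repressed outside their phase), a
cycling fraction declining linearly from 50% to 10% across stages, and an
optional human-only bimodal program in late-stage cells. The deep
generator multiplies library sizes tenfold, uses four stage groups with
stage-specific programs, and plants an exact number of QC-failing cells.

Problem sizes are chosen for desk-scale verification — 80 cells per type
(1,040 per species) for the default pair, ~2,000 cells for doublet
analyses (the index needs enough artificial doublets to cover the type-
pair combinations), 120–250 cells per stage for trajectories, and a
5,000-cell pool for the rare-subpopulation recovery — and the magnitudes
of library size and dispersion are testability choices, not estimates of
any particular dataset. What the generator does *not* emulate: ambient
RNA, gene-length/GC bias, zero inflation beyond the NB (dropout arises
from the NB itself), doublet-specific capture efficiencies, and realistic
correlation between programs. Passing tests therefore demonstrate that
the procedures recover what they assume, not that they are robust to
every artefact of real droplet data.

## Reproducibility

Every stochastic operation takes an explicit seed; `sim_config(seed =)`
derives per-operation seeds deterministically, and identical seeds give
bit-identical matrices. `scripts/acceptance.R` regenerates the study
conditions from scratch and recomputes the headline recovery numbers; the
test suite covers each operation with oracle equivalences (all-pairs kNN,
exhaustive rank-sum permutation, the TOM triple sum, direct
eigen-decomposition, projection identity) and planted-parameter recovery
across fixed-seed suites.
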