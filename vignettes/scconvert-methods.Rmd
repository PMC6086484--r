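---
title: "Models and methods behind scconvert"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scconvert}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`scconvert` analyses transcription-factor-driven direct conversion of
cochlear supporting cells (SCs) into hair-cell-like cells (cHCs) from three
kinds of expression data — droplet single-cell UMI counts, bulk RNA-seq of
sorted cell populations, and multiplex single-cell qPCR — plus imaging-based
conversion counts. This vignette explains the models each stage assumes, the
parameters that matter, what the bundled synthetic-data generator does and
does not emulate, and the numerical choices made where the design was open.

## The synthetic study conditions

All tests and the acceptance script run on data from the package's own
generator, because the pipeline's statistical behaviour — not any single
dataset — is the deliverable. `sim_config()` describes a small cochlear
census: seven populations of 100 cells each (SC1, SC2, cHC1–cHC3, OHC, IHC)
over 1,500 genes plus special features.

**Latent conversion coordinate.** Cells of the continuum populations
(SC1 → cHC1 → cHC2 → cHC3) carry a latent state $s \in [0,1]$, drawn
uniformly from consecutive, ordered sub-intervals; by default each
population occupies the central half of its quarter (`continuum_gap = 0.5`),
so the states are ordered *and* separated. The gap is the single dial
between "one smooth continuum" and "distinct stages"; the default was
chosen once so that graph clustering resolves the stages while pseudotime
still reads the ordering — mirroring how the real experiment shows discrete
clusters lying on a common trajectory.

**Marker programs.** Every population owns exclusive markers with a log2
elevation of 4 over a baseline drawn from an exponential law (most genes
low, few high — the familiar UMI regime). For continuum populations the
elevation is not a step function of population identity but a triangular
bump in $s$ (width 0.25 around the sub-interval midpoint), so expression
profiles change continuously along the conversion path and adjacent states
resemble each other more than distant ones. Without this, all populations
would be mutually equidistant in expression space and no trajectory method
could order them.

**Transgene model.** The HA-tagged transgene and endogenous Atoh1 share the
cell's $s$: their log2 means are $b + \lambda s + \varepsilon$, with
loading $\lambda = 4$, baseline $b = 6$ and independent Gaussian noise
(sd 0.25). A small hair-cell TF module (Barhl1, Lhx3, Gata3, Hes6, Neurod6)
is driven by the same $s$ with larger private noise (sd 1.05), which makes
the shared coordinate — read out through Atoh1 — the hub of the
co-expression network rather than any one target. A tdTomato reporter marks
the Cre lineage. The loadings and noise scales were calibrated once so the
preset reaches the qualitative regimes of interest (a strong
transgene–endogenous correlation, a ~3-fold transgene increase between the
least and most converted states, an Atoh1-centred network); the exact
values the preset produces (R² ≈ 0.6–0.7, fold ≈ 2.6–3.0 after
library-composition damping) are properties of the preset, not claims
about any dataset. Deeper simulated libraries push R² higher; at droplet
depths counting noise caps it.

**Counts.** Per-cell expected fractions are the population profile (with
the cell's special-feature values patched in) normalized to sum to one,
scaled by a log-normal library size (median 2,500 UMIs, sdlog 0.35), and
counts are negative-binomial with variance $\mu + \mu^2/\theta$
($\theta = 2$ for background genes, $\theta = 50$ for the highly expressed
latent features). One RNG stream per artifact is derived from the master
seed, so the UMI matrix, bulk tables, qPCR plates and count tables are
independently reproducible.

**What is not emulated:** ambient RNA, doublets, cell-cycle heterogeneity
(the workflow assumes G1-filtered input and offers only a label-based
filter), batch effects beyond replicate labels, and gene–gene correlation
beyond the marker/latent structure. Passing tests therefore demonstrate
correctness of the algorithms under a clean generative model, not
robustness to every artifact of real droplet data.

## Single-cell preprocessing

*Library-size QC* removes, per sample, cells outside quantile bounds of the
total-UMI distribution (default 2%–98%, linear-interpolation quantiles).
Per-sample filtering matters because samples differ in depth; a fixed
global cutoff would bias composition.

*Depth harmonization* replaces each cell's counts with
$y_{gc} \sim \mathrm{Binomial}(\min_c T_c,\; x_{gc}/T_c)$ drawn
independently per gene. The expectation of each cell's new total equals the
reference depth; because the binomials are independent, realized totals
vary around it. A `mode = "multinomial"` option fixes totals exactly and is
documented as a deviation from the per-gene binomial definition. Zeros stay
zeros, and composition is conserved up to Monte-Carlo error.

*HVG selection* works on $\log_2(\text{count}+1)$: dispersion is
variance/mean, genes are binned into 20 equal-frequency mean bins,
dispersion is z-scored within bins, and genes with $z \ge 1$ are kept. Bins
left with fewer than two genes are merged downward with a warning. The
z-scoring-within-mean-bins construction removes the mean–dispersion trend
without fitting a parametric curve.

## Clustering and markers

Distances are Euclidean over the top 30 PCs of the gene-centered
log-expression of HVGs. The SNN graph uses $k = 20$ neighbors (each cell's
neighbor set includes itself, the convention under which mutual nearest
neighbors attain weight 1 and a complete neighborhood gives exactly 1);
Jaccard weights below 1/15 are pruned. Community detection maximizes the
weighted modularity $Q=\sum_c [L_c/m - (d_c/2m)^2]$ by a Louvain scheme
with a fixed node-visit order and ties broken toward the lower community
label, so results are bit-reproducible. Graphs with at most eight nodes are
instead solved *exactly* by enumerating all set partitions — greedy
agglomeration has provable local optima even on a six-node path — and the
reported Q is always re-evaluated from the returned partition with the
formula above, never taken from the optimizer's internal state.

Markers are one-vs-rest two-sided Wilcoxon tests on log expression,
restricted to genes with a log2 mean difference ≥ 0.25 detected in ≥ 10% of
in-cluster cells, with BH correction across all tests performed.

## Pseudotime

Ordering genes require mean expected count ≥ 0.1 and empirical dispersion
(variance/mean) ≥ 1 after censoring values below a detection limit of 0.5.
The trajectory itself is a deliberately transparent principal tree:
k-means centroids (default 10) in the PC space of the ordering genes,
a minimum spanning tree over the centroids, and orthogonal projection of
each cell onto its nearest tree edge. This replaces reversed-graph-embedding
trajectory methods with an object that satisfies the same contract — a tree
plus geodesic pseudotime — while remaining fully testable; the package does
not attempt to reproduce any specific embedding. Pseudotime is the
normalized geodesic distance from the root centroid (the tree node nearest
the root cluster's centroid). If the root cluster spans several tree nodes,
cells "behind" the root fold onto small positive τ; at the default
conditions this affects at most a few cells.

Pseudotime dependence is tested per gene by a likelihood-ratio test of a
natural cubic spline in τ (3 df, Gaussian working likelihood on log
expression) against an intercept-only model, with $n\log(RSS_0/RSS_1)$
compared to $\chi^2_3$ and BH correction. The working-likelihood choice
keeps the test exact on its stated scale and empirically holds its size
(type-I error 0.046–0.056 at $\alpha=0.05$ for $n$ of 145–300 in the
package's own calibration runs); a branch label can be added as a covariate
to both models to test pseudotime beyond branch membership. Binned
profiles average log expression in 100 equal-width τ bins, linearly
interpolating empty bins.

## TF co-expression network

Nodes are TF-list genes detected in ≥ 10 cells with log-scale variance
> 0.4; edges connect pairs with squared Pearson correlation above 0.25,
keeping the sign of r. The threshold is applied to R² alone — no p-value
gate — because with hundreds of cells every |r| > 0.5 is overwhelmingly
significant anyway; a p-value option can be layered on by filtering the
returned edge table. Communities come from the same deterministic
modularity engine (unweighted edges), and each community's top-degree gene
is reported as its hub.

## Bulk RNA-seq

TMM normalization (30% trim on M, 5% on A, precision weights, factors
rescaled to geometric mean 1) is delegated to edgeR, the reference
implementation; the test suite verifies it against an independently coded
direct evaluation of the trimmed-mean formula. FPKM is
count / total × 10⁶ / (length/1000). Differential expression uses
voom precision weights with limma's moderated t and BH FDR per contrast;
"trimming" of the count matrix is read as low-expression filtering
(CPM > 1 in ≥ 2 samples). The TF subset takes genes significant in any
pairwise contrast (FDR < 0.05) intersected with the TF list —
union-of-pairwise rather than an omnibus F, with the F-test reachable by
supplying a single joint contrast set.

The distance suite compares cell-type mean profiles (TMM-normalized FPKM,
log scale, all-zero genes removed) under six metrics: 1 − Spearman ρ on all
genes and on TF genes, and Euclidean distance in PC space of all genes, TF
genes, the top 200 genes by MAD, and genes with ≥ 4-fold change across cell
types. The bulk generator's converted-cell profile is a convex combination
(weight 0.75) of the neonatal-hair-cell effect and the supporting-cell
effect, so the generative truth places cHCs nearest neonatal OHCs under any
sensible metric — the qualitative configuration the distance suite is meant
to detect. Bulk defaults (10 M fragments, NB size 100, i.e. ~10% CV between
duplicates) describe good-quality bulk libraries; duplicate rank
correlations then comfortably exceed the 0.85 concordance floor.

## Single-cell qPCR

Calibration uses a threefold dilution series of 15 points per assay: the
LOD-Ct is the highest observed Ct, the universal LOD-Ct the median across
assays, and efficiency is $10^{-1/\text{slope}} - 1$ from the least-squares
slope of Ct on $\log_{10}$ concentration (base-10 regression regardless of
the dilution factor, standard practice). Melt-curve QC drops chambers with
more than one peak. Expression is $\log_2(Ex) = \text{LOD-Ct} - Cq$, with
either per-assay or universal LOD (both exposed; per-assay is the default),
non-amplifying chambers mapped to the detection floor 0, negative values
clipped to 0, and chambers removed by QC left as missing (NA) rather than
zero — conflating "no measurement" with "no expression" visibly distorts
group means. Assay-level failure rates are reported by
`assay_missingness()`. Group comparisons are one-way ANOVA with pairwise
Student's t-tests under Bonferroni correction (m = number of pairs) behind
an ANOVA gate at 0.05. Cross-platform concordance correlates per-gene
log-ratios of group means between platforms; on paired synthetic data with
shared truth and 0.3 log2 units of platform noise it sits at r² ≈ 0.9.

## Classifier validation and conversion rates

The cluster-validation protocol asks whether held-out expression predicts
cluster labels: a stratified 80/20 split per cluster, min-max scaling and
30-component PCA (no whitening) fitted on training cells only, an RBF-SVM
grid-searched over C ∈ {0.1, 1, 10, 100} and γ ∈ 10^{−3..1} with 3-fold CV,
and confusion-matrix accuracy on the held-out cells. The grids are common
defaults; the fitted transform is exposed so tests can verify that
corrupting held-out cells changes nothing about it (no leakage). On the
default preset the protocol reaches 100% held-out accuracy — the clusters
are real, separable states.

Conversion rates divide double-positive by reporter-positive cells after
removing dislodged endogenous hair cells from both numerator and
denominator. Comparisons treat per-sample rates as the units (matching
scatter-plots of samples): Student's t for pairwise designs, a two-way
factorial ANOVA (factor presence parsed from condition names) for
co-reprogramming designs, where synergy appears as the interaction term.

## Problem sizes and determinism

Default analysis sizes — 700 cells × ~1,500 genes for clustering and
validation, 600 cells for trajectory work, 2,000 genes × 10 samples for
bulk, 48 assays × 68 cells for qPCR — were chosen as the smallest scales at
which every statistical property of interest (cluster recovery, pseudotime
recovery, test calibration, detection sensitivity) is stable across seeds.
Every stochastic step takes an explicit seed; artifact-specific streams are
derived from it, so any single output can be regenerated without rerunning
the rest.

## Known limitations

The principal tree assumes the trajectory is tree-shaped and is fit in a
fixed PC space; cyclic or disconnected topologies are out of scope. The
spline LRT relies on a Gaussian working likelihood on log counts — adequate
for depth-harmonized UMI data, but a negative-binomial variant would be
preferable for raw counts. The greedy modularity optimizer guarantees
optimality only for graphs small enough to enumerate. The generator's
populations are balanced and its noise is unstructured, so the suite does
not probe sensitivity to rare populations or correlated technical noise.
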