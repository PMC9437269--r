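---
title: "primingkit: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{primingkit: models, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`primingkit` packages the statistical machinery used to establish
transcription-factor-dependent enhancer priming in hematopoietic
multipotent progenitors: when a lineage-determining factor such as EBF1 is
lost, a set of regulatory elements loses chromatin accessibility, the
factor's footprint disappears from the Tn5 cut-site signal, partner-motif
co-occurrence at those elements becomes detectable against background, and
the transcriptome of the progenitors drifts toward the competing (myeloid)
fate. Each of those observations corresponds to one statistic in this
package:

* negative-binomial differential testing of count matrices
  (ATAC peaks and pseudobulk expression share one engine),
* a motif-pair co-occurrence z-score against background peak subsamples,
* motif-centred aggregation of Tn5 cuts with a randomised control
  envelope and a scalar footprint depth,
* enhancer-anchored preranked gene-set enrichment (weighted
  Kolmogorov-Smirnov),
* a direction-of-transition (DoT) score on a single-cell reference
  landscape, and
* query-to-reference cell projection through a PCA rotation and
  nearest-neighbour regression.

All of it is exercised on seeded synthetic data whose generators are
first-class, tested code (`generator_config()`, `gen_peaks()`,
`gen_counts()`, `gen_cut_track()`, `gen_landscape()`), and chained end to
end by `run_scenario()`.

Read alignment, peak calling, Tn5 sequence-bias correction, enhancer-model
training, batch-correction and graph-clustering algorithms are outside the
package: their outputs (peak sets, cut tracks, enhancer probabilities,
corrected coordinates, cluster labels) are inputs here.

# Differential count testing

`test_differential()` fits, per feature, a negative-binomial log-linear
model with a log link, log-size-factor offsets and a fixed per-feature
dispersion, and tests the group coefficient with a Wald statistic referred
to a t distribution with `residual + prior` degrees of freedom.

**Normalisation.** Library size factors are median-of-ratios (ratio of
each sample's count to the feature's geometric mean, median over features
with all-positive counts), falling back to total-count factors when no
feature has a defined geometric mean. The factors are rescaled to
geometric mean 1, so offsets are centred.

**Dispersion.** A method-of-moments estimate
$\hat\phi = (s^2 - \bar y)/\bar y^2$ is computed from group-centred,
normalised counts and shrunk toward a mean-dispersion trend
(`stats::lowess` of the raw estimates against log mean) with weight
$w = d_0/(d_0 + d)$, where $d$ is the residual degrees of freedom and
$d_0$ the prior (default 6). Shrinkage happens on the raw scale so that
Poisson-like data (whose raw moment estimates straddle zero) end up at the
floor $\phi_{\min} = 10^{-4}$ rather than being inflated by a log-scale
average; zero-variance features are pinned to the floor.

**Inference.** The moderated reference distribution
$t_{d + d_0}$ mirrors the usual empirical-Bayes accounting: the shrunk
dispersion behaves like a variance estimate with $d + d_0$ degrees of
freedom. The contract of this engine is *calibration and recovery*, not
numerical identity with any particular quasi-likelihood implementation:
under the global null the p-value distribution is uniform (fraction below
0.05 within [0.035, 0.065] in the test suite) and zero features are
called at FDR 0.1 in the large majority of seeded runs, while planted
two-fold-squared effects ($|\log_2 FC| = 2$, $\phi = 0.1$, $n = 4$ vs 4)
are recovered with recall above 0.8 at empirical FDR below 0.15. An
independent edgeR quasi-likelihood route is used in the tests as a
cross-check (log-fold-change correlation > 0.995), never as the
implementation.

**Classes and thresholds.** Features are classed `reduced` / `gained` /
`ns` at FDR < 0.1 (KO − WT orientation, i.e. the second level of the
group factor against the first). Pseudobulk expression calls additionally
require $|\log_2 FC| \ge 0.2$. The bulk expression filter keeps a gene
when its mean count within at least one condition strictly exceeds 100.
All of these constants live in `analysis_config()` and are serialised
into run manifests. No fold-change shrinkage is applied: the reported
log2FC is the GLM estimate (display-oriented shrinkage is a deliberate
omission).

**Annotation.** `annotate_peaks()` assigns each peak to the gene whose
TSS-anchored window (20 kb upstream to 10 kb downstream, in gene
orientation) contains the peak centre; among several candidates the
smallest centre-to-TSS distance wins, remaining ties break
lexicographically by gene id so results are deterministic.

# Motif co-occurrence

`scan_motifs()` scores every position of every peak on both strands with
the motif's log2-odds matrix (probabilities pseudocounted and
renormalised; `N` scores zero, i.e. as background) and reports positions
at or above the threshold, reverse-strand hits in forward-frame
coordinates. The default threshold is 80% of the motif's maximal
log-odds; an absolute threshold can be given. Scanning is deliberately
re-implemented in-package (rather than delegated) so that threshold
semantics, `N` handling and strand reporting are fully specified; an
exhaustive per-position rescoring oracle in the tests guards it.

`count_cooccurrences()` counts pairs of hits (one of motif A, one of B)
lying in the *same peak* whose **nearest-edge gap** is at most 50 bp
(overlapping occurrences count as distance 0). Design choices, each
exposed as an option because the underlying convention is genuinely open:

* *Distance anchor*: edge gap is the default because it is invariant to
  motif length; centre-to-centre is available (`anchor = "center"`).
* *Multiplicity*: all qualifying pairs are counted by default; a
  per-peak indicator mode (`per_peak = TRUE`) is available.
* *Within-peak restriction*: co-occurrence within a shared element is the
  biological object, and background sets are peak subsamples, so
  cross-peak pairs would not be well defined under subsampling.
* When A = B, each unordered pair of distinct hits counts once.

`cooccurrence_zscore()` compares the observed count in a target peak
subset with the counts in 1,000 equally sized random subsamples (without
replacement) of the peak universe:
$z = (\mathrm{obs} - \overline{c_{bg}})/\mathrm{sd}(c_{bg})$, with the
sample SD and the convention $z = 0$ when the SD is zero (degenerate
universe). The full background vector is retained for audit. Because
pairs are within-peak, the count of any subset is a sum of precomputed
per-peak counts, which makes the 1,000 subsamples cheap. Null calibration
(target itself a random subsample) gives mean z near 0 and SD near 1;
a planted pair burden (2% baseline vs 40% in the target) stands out at
z > 5, the display threshold used for reporting co-occurrence heatmaps.

`motif_enrichment()` is the companion per-motif test: a one-sided Fisher
exact test on the 2x2 table of peaks with/without a hit in target vs
control, the control being either the reciprocal differential peak set or
a seeded mononucleotide shuffle of the target sequences. The reported
odds ratio is the sample odds ratio (the conditional MLE from
`fisher.test` is also returned).

# Tn5 footprints

`aggregate_cuts()` averages per-base cut counts in windows of half-width
`w` (default 100 bp — the original plots do not print their window, so it
is configurable) centred on motif hits, reversing minus-strand windows so
profiles are motif-oriented; sites whose window leaves the peak are
dropped and counted. `control_envelope()` repeats the aggregation for 100
random sets of control-motif sites (CTCF by convention) and summarises
the ensemble by per-base median and SD. `footprint_depth()` reduces a
profile to a scalar: mean over the flank bases (the outer half of the
window on each side) minus mean over the core (motif half-width);
positive depth means central protection. A candidate condition shows a
footprint when its depth exceeds the control-set depth distribution; the
knockout condition should stay inside it.

The package consumes an existing per-base cut track (bedGraph; raw or
bias-corrected — the report states which); insertion-bias modelling is a
separate method and out of scope.

# Enhancer-anchored GSEA

The ranked list is built from the peak-level differential result
restricted to enhancer peaks (probability strictly > 0.8, from the BED
score field) that carry a gene annotation: per peak
$r = \log_2 FC \cdot (-\log_{10} FDR)$, FDR floored at $10^{-300}$
before the log. Per gene the peak with the largest $|\log_2 FC|$ is
retained. The printed rule says "highest fold change"; because the
analysis is two-sided (a lymphoid and a myeloid signature), the absolute
value is the default reading, with `dedup = "signed"` available. Final
ties break by gene id.

Signature sets are built from a reference two-population comparison
(CLP-like vs GMP-like): candidates at FDR < 0.05 and $\log_2 FC$
strictly beyond ±2, keeping up to 300 genes of smallest FDR per
direction (ties: larger $|\log_2 FC|$, then gene id).

`enrichment_score()` is the classic weighted Kolmogorov-Smirnov running
sum (hit increments $|r|^p / \sum_{set} |r|^p$, miss decrements
$1/(N - |set|)$, $p = 1$ by default, ES = signed extremum).
`permutation_pvalue()` draws 1,000 random gene-label sets of the same
effective size and reports

$$p = \frac{1 + \#\{|ES_{null}| \ge |ES|\}}{n_{perm} + 1},$$

comparing magnitudes over the *whole* null ensemble. Restricting the
comparison to sign-matched null scores while keeping the
$(n_{perm}+1)$ denominator would make null p-values uniform on
$(0, \tfrac12)$ rather than $(0,1)$; the two-sided magnitude comparison
keeps the null uniform while preserving the attainable minimum
$1/(n_{perm}+1)$. NES follows the standard sign-matched convention:
ES divided by the mean $|ES_{null}|$ of matching sign.

# Single-cell landscape operations

**QC and sex.** Cells with fewer than 1,200 detected genes (count > 0)
are excluded (strict). Sex labels are definitional on marker detection:
female-marker (Xist-like) expression without any Y-linked gene gives
`female`, the converse `male`, both `excluded_doublet`, neither
`excluded_undetermined` — an exhaustive partition.

**Normalisation and reduction.** Counts are scaled per cell to the median
total and log1p-transformed. Highly variable genes are ranked by
within-bin normalised dispersion (variance/mean of the log-normalised
values, z-scored within 20 mean-expression quantile bins), honouring an
exclusion list (the perturbed gene, sex markers and cell-cycle genes in
the emulated design; 7,000 genes and 50 PCs for real-scale data). PCs
come from `prcomp` on the standardised HVG columns; the rotation and the
per-gene moments are stored for projection.

**Cell-cycle-style scores.** `cell_cycle_score()` is the binned-control
score: mean over the set minus mean over control genes drawn per set gene
from the same mean-expression bin (25 bins, 50 controls per gene,
seeded). All set genes are removed from the control pools — otherwise a
coherently shifted set contaminates its own controls and the score
deflates; when a bin holds only set genes the pool falls back to all
non-set genes.

**DoT.** The published score's formula is defined operationally here:
for cell $c$, $\mathrm{raw}_c = \sum_g \Delta_g (x_{cg} - \bar
x^{origin}_g)$ over the perturbation's differential genes, with
$\Delta_g$ the log2 fold change and $\bar x^{origin}$ the mean
log-normalised expression over the origin cells — so the origin mean
score is exactly zero, the score is linear in the weights, and flipping
every sign negates it. Positive values mark cell states the perturbation
moves toward. Per-cell z-scores come from 100 seeded null draws in which
each weight is reassigned to a random gene from the same
mean-expression bin. The exact normalisation of the original score is
not restated in the source analysis; this operational definition is a
declared stand-in and is flagged as such in reports.

**Projection.** Query cells are aligned to the reference in two steps
standing in for the original iterative batch-correction stage: (1) one
*global* location-scale map takes the query's pooled expression moments
(over all shared HVG entries) to the reference's — this cancels
platform-wide affine distortions exactly while leaving between-gene
structure intact even when the query is a homogeneous cell population;
(2) per-gene standardisation to the reference mean/SD places the query in
the space the reference PCs were computed in. Query PCs are the
standardised matrix times the reference rotation; the 15 nearest
reference cells (Euclidean, PC space) supply corrected-PC and embedding
coordinates as their unweighted mean (inverse-distance weighting by
flag), so predictions lie in the neighbours' convex hull, dimension-wise.
A per-gene correction was rejected: estimated from a homogeneous query it
would erase exactly the signal being projected. Acceptance of this stage
is neighbour recovery (self-projection exact at k = 1; distorted
self-projection exact; cluster-restricted queries recover their cluster
label), not coordinate identity with any particular correction method.

# The synthetic-data generators

The generators reproduce the *statistical structure* of the study's
inputs, with ground-truth records for every planted signal, and
byte-identical regeneration under a fixed seed (every generator draws
from a stream derived from the master seed).

* **Peaks** (`gen_peaks()`): i.i.d. background nucleotides at
  configurable frequencies (uniform by default — no dinucleotide
  structure, which is sufficient for PWM-scan testing but means shuffle
  controls are trivially calibrated); peak lengths uniform in 300-600 bp
  on a synthetic chromosome. Planted motif instances are written at
  recorded offsets and strands; at the default fidelity of 1 the
  consensus is planted, so every planted occurrence attains the maximal
  PWM score and recovery is exact at any threshold (sub-consensus
  sampling is available via `plant_fidelity`). A configured fraction of
  peaks carries an A-B pair at a nearest-edge gap drawn from 0-50 bp.
  Enhancer probabilities are drawn high for motif-bearing peaks.
* **Counts** (`gen_counts()`): feature-wise negative binomial with
  log-uniform baseline means (20-500), per-feature dispersions from a
  configured range, per-sample depth factors U(0.7, 1.3) so
  normalisation is exercised, 4 replicates per genotype, and planted
  signed log2 effects on a recorded feature subset. Optional additive
  sex/batch log2 effects.
* **Cut tracks** (`gen_cut_track()`): Poisson cuts at a uniform
  background rate within peaks; in the bound condition, planted footprint
  sites (sites of the designated bound motifs only — control-motif sites
  stay unbound) multiply the rate by a symmetric trapezoid: full
  depletion of the configured depth over the motif core, linear ramp
  back to background over ±10 bp. The original plots do not state a
  footprint shape; the trapezoid is the simplest shape with a core and
  shoulders.
* **Landscape** (`gen_landscape()`): cells on a branched 2-D manifold
  (origin cluster at the root, other clusters at radiating tips; the
  lineage coordinate is the distance from the root), cluster-marker
  genes (log2-elevated in their home cluster), smooth gradient genes,
  one female and three Y-linked sex markers whose detection is
  guaranteed in the carrying cells (labels are definitional, so sex
  assignment can be validated exactly; a configured doublet fraction
  expresses both), mice split into genotype blocks with alternating sex
  and paired batches (so group, sex and batch stay non-collinear in
  covariate designs), and a planted knockout expression shift in one
  cluster that targets that cluster's own markers first — making the
  perturbation point toward that cell state, as a lineage-biasing
  perturbation does. Counts are NB with per-cell library sizes; PCs are
  computed by the package's own reduction and double as the "corrected"
  coordinates (no batch effect is simulated by default), and the true
  manifold coordinates serve as the 2-D embedding.

What the generators do **not** emulate — and hence what passing tests do
not show about real data: genomic sequence composition (GC/dinucleotide
bias, repeats), fragment-level Tn5 sequence bias, mouse-level biological
variance components beyond the NB dispersion, ambient RNA and detailed
doublet structure, batch effects on the embedding, and realistic genome
coordinates. Conclusions from the synthetic validation concern the
*statistics*, not upstream data-quality issues.

# Numerical choices

* Dispersion floor $10^{-4}$; FDR floor $10^{-300}$ before $-\log_{10}$.
* IRLS for the NB GLMs: shared design across features, vectorised
  weights, closed-form 2x2 solves for single-factor designs, linear
  predictor clamped to ±30, convergence at $\max|\Delta\beta| <
  10^{-10}$ or 30 iterations.
* Ties: annotation (distance, then gene id), ranked lists (rank, then
  gene id), signature sets (FDR, then $|\log_2 FC|$, then gene id) —
  all deterministic.
* Degenerate inputs: zero-SD backgrounds give z = 0 by convention;
  a universe equal to the target warns; empty expression filters warn
  rather than error; clusters without replication are skipped with a
  logged reason; rank-deficient designs error naming the confounded
  factors.
* Seeds: one master seed per run; each stochastic stage derives its own
  stream (`seed`-and-stride), so stages are reproducible independently of
  evaluation order, and all derived seeds stay below $2^{31}$.

# Problem sizes

The shipped validation uses desk-scale sizes chosen to estimate each
property with comfortable Monte-Carlo margins: 2,000-peak universes with
200-peak targets and 1,000 background subsamples (200 replicates for null
calibration of the z-score), 5,000-feature count matrices at 4 vs 4 over
50 null seeds, 100-control-set footprint envelopes over 400 peaks,
200-gene ranked lists with 1,000 permutations (200 replicates for p-value
uniformity), and landscapes of 1,200-2,000 cells by 600-1,000 genes with
5 clusters. The end-to-end scenario (`default_recipe()`) uses 2,000
peaks, 8 samples, and a 2,000 x 1,000 landscape. The headline counts of
the original study (hundreds of differential sites among tens of
thousands of peaks, tens of thousands of cells) derive from the deposited
sequencing data and are not reproduced at these scales; the validation
targets are the calibration and recovery properties stated above.

# Known limitations

* The NB engine is a Wald test with moderated dispersions, not a
  quasi-likelihood F-test; very small samples (2 vs 2) lean heavily on
  the trend prior.
* Median-of-ratios size factors are biased when a large fraction of
  features moves in one direction (a 20% one-sided differential burden
  shifts the factors enough to create opposite-direction false calls);
  this is a property of the normalisation, shared with standard
  implementations, and visible in the end-to-end scenario's extra
  `gained` calls.
* The co-occurrence background preserves peak count only — not length or
  composition of the target subset (no GC- or length-matched sampling).
* The DoT null reassigns weights to bin-matched genes independently,
  ignoring gene-gene correlation; z-scores are therefore comparative,
  not calibrated p-values.
* Projection assumes the query shares the reference's HVG space (≥ 50%
  overlap enforced) and that a global location-scale correction is an
  adequate stand-in for batch correction across platforms.
* The scenario report flags planted-finding recovery with fixed
  significance conventions (Fisher p < 0.05, z > 5, envelope exceedance,
  GSEA p < 0.05); these are reporting conventions, not tuned values.
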