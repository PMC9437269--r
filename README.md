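# primingkit

Statistics for detecting transcription-factor-dependent **enhancer
priming** and **lineage bias** in hematopoietic multipotent progenitors
(HSC/MPP compartment). The package is aimed at regulatory-genomics
analysts who have peak sets, count matrices, cut-site tracks and a
single-cell reference landscape in hand and need the downstream
statistics as tested, reusable functions rather than one-off scripts.

When a lineage factor (e.g. EBF1) is deleted, four signatures appear in
the data, and each has a dedicated statistic here:

| Observation | Statistic | Function |
|---|---|---|
| Regulatory elements lose accessibility in the knockout | NB GLM with moderated Wald *t*, BH FDR, `reduced`/`gained` classes | `test_differential()` |
| Partner motifs co-occur in the affected peaks | pair count within 50 bp vs 1,000 background peak subsamples, z-score | `cooccurrence_zscore()` |
| The factor's Tn5 footprint is genotype-specific | motif-centred cut aggregation vs 100 random control-motif sets, depth statistic | `aggregate_cuts()`, `control_envelope()`, `footprint_depth()` |
| The transcriptome drifts toward the competing fate | enhancer-anchored preranked GSEA (rank = log2FC·(−log10 FDR)); DoT score on a reference landscape | `build_ranked_list()`, `permutation_pvalue()`, `dot_score()` |

plus pseudobulk differential expression (`pseudobulk()` +
`test_differential()` with sex/batch covariates), query-to-reference cell
projection (`project_cells()`), and seeded synthetic-data generators for
every input (`gen_peaks()`, `gen_counts()`, `gen_cut_track()`,
`gen_landscape()`), with ground-truth records.

Core model, in brief: counts $y_{ij}$ follow
$\mathrm{NB}(s_j \mu_{ij}, \phi_i)$ with $\log \mu_{ij} = x_j^\top
\beta_i$; $s_j$ are median-of-ratios size factors, $\phi_i$
method-of-moments dispersions shrunk to a mean-dispersion trend, and the
group coefficient is tested with a Wald statistic against
$t_{d + d_0}$. Co-occurrence significance is
$z = (c_{obs} - \bar c_{bg})/\mathrm{sd}(c_{bg})$ over seeded
subsamples; GSEA is the weighted Kolmogorov–Smirnov running sum with
gene-label permutations; the DoT score is
$\sum_g \Delta_g (x_{cg} - \bar x^{origin}_g)$ with an
expression-matched random-gene null. The methods vignette
(`vignettes/primingkit-methods.Rmd`) documents every model, default and
design decision.

## Worked example

The whole analysis can be exercised end to end on one seeded synthetic
scenario in which peaks carrying a planted EBF1-like motif (some with a
C/EBP-partner motif within 50 bp) lose accessibility in the knockout,
carry wild-type-only footprints, and sit at enhancers of lymphoid
signature genes, while a myeloid gene set gains:

```r
library(primingkit)
res <- run_scenario(default_recipe(seed = 1), out_dir = "scenario_out")
```

which logs, stage by stage:

```
[simulate] 2000 peaks (400 motif-bearing reduced, 150 gained), 2000 x 8 counts
[da] 398 reduced, 203 gained at FDR<0.1
[cooc] motif OR=12039.7 (p=0); pair z=21.25 (obs=400, bg=80.6)
[footprint] depth WT=0.404 KO=0.002 (control -0.002 +/- 0.020)
[gsea] CLP ES=-0.91 p=0.000999 | GMP ES=1.00 p=0.000999
[landscape] pseudobulk shift recall=1.00 (52 DE genes); max DoT z in cluster 5
```

Reading the numbers: 398 of the 400 motif-bearing peaks are recovered as
`reduced` at FDR < 0.1 (the extra `gained` calls beyond the 150 planted
reflect the usual size-factor bias under a one-sided differential
burden); the EBF1–C/EBP pair co-occurs far above background (z = 21.2,
well past the z > 5 display threshold); the wild-type footprint depth
(0.404) stands outside the 100-set CTCF control envelope (−0.002 ±
0.020) while the knockout depth (0.002) sits inside it; the lymphoid
(CLP) signature is enriched on the wild-type side of the enhancer ranks
(negative ES) and the myeloid (GMP) signature on the knockout side, both
at the attainable minimum permutation p = 1/1001; and the planted
knockout shift is fully recovered by pseudobulk DE, with the DoT score
peaking in the shifted (myeloid-most) cluster. `scenario_out/` holds
every intermediate in standard text formats (BED, FASTA, bedGraph, TSV,
an MTX landscape bundle), `report.md`, and `manifest.json` with content
hashes and the per-stage filter cascade.

Individual pieces work standalone, e.g.:

```r
cfg <- generator_config(seed = 11, n_peaks = 800)
pk  <- gen_peaks(cfg)
hits_a <- scan_motifs(pk$peaks, cfg$motifs$EBF1)
hits_b <- scan_motifs(pk$peaks, cfg$motifs$CEBPA)
```

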