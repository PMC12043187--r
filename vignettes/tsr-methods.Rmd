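---
title: "Methods: quantifying temperature-induced sex reversal from sequencing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying temperature-induced sex reversal from sequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsrseq)
```

# Scope

`tsrseq` implements the statistical core of a temperature-induced sex
reversal (TSR) study in Nile tilapia: high-temperature rearing during a
critical developmental window converts a fraction of genetically female
(XX) fish into phenotypic (pseudo)males. The package covers the analysis
stages from raw gene counts through normalized expression, differential
expression, temperature-response clustering, integration with histone-mark
ChIP profiles, intron-retention isoform quantification of a kdm6bb-like
locus, cohort-level sex-reversal statistics and subcellular localization
ratios — each stage paired with a simulator that plants known ground truth
so every estimator can be scored.

The experimental frame is five temperature-sex groups (XX28F, XY28M,
XX36F, XX36P pseudomales, XY36M) sampled at four gonadal stages (10, 12,
15, 20 days post-fertilization) with three biological replicates.

# Simulation model

`sim_design()` + `simulate_counts()` draw negative-binomial counts
`NB(mu, 1/dispersion)` per gene and sample. A planted cluster table shifts
means multiplicatively: Temp-up genes gain `2^effect` in every 36 °C
group, Temp-down genes lose it, male-biased genes gain it in XY28M,
female-biased genes in XX28F. Per-sample depth factors are log-normal with
coefficient of variation `lib_size_cv` (default 0.2). Defaults: 2000
genes, base mean 100, dispersion 0.1, and a cluster spec mirroring a
whole-transcriptome screen (15% heat-up, 12% heat-down, about 1%
sex-biased each way, effect 2 on the log2 scale).

What the generator deliberately does *not* emulate: read-level alignment
noise, gene length and GC effects, batch structure, and correlated
dispersion across genes. It produces gene-level counts whose first two
moments match the negative-binomial working model of the tests, which is
exactly what is needed to verify calibration and power of the downstream
statistics, not to benchmark aligners.

# Normalization

`tmm_factors()` computes trimmed-mean-of-M-values (TMM) scaling factors
(log-ratio trim 0.3, absolute-intensity trim 0.05, reference = the sample
whose upper quartile is closest to the mean upper quartile), renormalized
to geometric mean one. The normalized unit from `normalize_counts()` is
counts per million after factor adjustment:
`cpm = count / (lib_size * factor) * 1e6`. The same machinery normalizes
ChIP peak-count matrices (counts per million mapped fragments, CMM).

A practical note verified in the test suite: TMM factors are exactly
invariant to a pure depth change of the *whole* matrix, but only
near-exactly invariant to doubling a single sample, because the trimmed
mean uses inverse-variance precision weights that depend on absolute
depth.

# Differential expression

`de_test()` is a fully specified two-group negative-binomial Wald test on
the normalized scale:

- normalized counts `q = count / (lib_size * factor / 1e6)`;
- per-feature method-of-moments dispersion
  `a = (var(q) - mean(q) * mean(1/s)) / max(mean(q), c)^2` per group,
  pooled by degrees of freedom and floored at `1e-4`;
- fold change `log2fc = log2((mean2 + c) / (mean1 + c))` with pseudocount
  `c = 0.5`;
- a delta-method standard error for `log2fc` and a Wald statistic
  referred to a *t* distribution with `n1 + n2 - 2` degrees of freedom.

The *t* reference (rather than the asymptotic normal) is a deliberate
small-sample calibration choice: at three replicates per group the plug-in
dispersion makes the normal reference anticonservative, while the *t*
reference keeps the measured type-I rate near nominal (0.049 at 10,000
null genes, 3 vs 3, dispersion 0.1). The DEG gate is the study's printed
rule — raw `P < 0.05` and fold change above two (`|log2FC| >= 1`);
`padj` (Benjamini–Hochberg) is reported for information only.
`temperature_degs()` runs the 36 vs 28 comparison per stage with
genotypes pooled and unions the per-stage DEG sets.

# Temperature-response clusters and gene taxonomy

`temperature_clusters()` z-scales each DEG's 20-point group-by-stage mean
profile and runs k-means (`k = 2`, 25 restarts, seeded). Cluster numbers
are arbitrary, so clusters are relabeled semantically: a centroid whose
mean over the 36 °C profile points exceeds its mean over the 28 °C points
is `Temp-up`, otherwise `Temp-down`. `sex_bias()` labels the 28 °C
male-vs-female DEGs, and `gene_taxonomy()` intersects the two labelings
into the four-way taxonomy `M-T_up`, `M-T_down`, `F-T_up`, `F-T_down`.
`trajectory_ratio()` then tracks, per taxonomy cluster and stage, the mean
pseudomale-to-female expression ratio (XX36P over XX28F group means, with
pseudocount 0.5 guarding empty denominators).

# Epigenome integration

All interval work uses BED-convention 0-based half-open coordinates.
`merge_peaks()` unions overlapping-or-touching peak calls into a disjoint
reference set; `annotate_peaks()` assigns each peak to its nearest TSS (by
peak midpoint, ties broken lexicographically and flagged) and classifies
it `promoter` (strand-aware TSS ± 3000 bp window) > `genic` >
`intergenic`; `count_fragments()` counts fragments sharing at least one
base with each peak.

`integrate_correlation()` correlates, per gene (or per cluster of genes),
the z-scaled expression profile over the five temperature-sex group means
at 20 dpf with the mean z-scaled CMM signal of the gene's promoter and
genic peaks, via Pearson correlation over the five points.
`screen_by_pcc()` retains units beyond a signed threshold of 0.5 —
negative for the repressive mark H3K27me3, positive for the activating
H3K4me3. Five points is few; the screen is a triage rule, not an
inferential test, which is why no P-value is attached.

# Isoform quantification by intron retention

`kdm6bb_model()` is a synthetic stand-in for the kdm6bb locus: ten 150-bp
exons, introns of 300 bp except the alternatively retained I5 (400 bp)
and I8 (500 bp). The isoform universe is `I5_dI8` (intron 5 retained),
`dI5_I8` (intron 8 retained — the nuclear-localizing form) and `dI5_dI8`
(both spliced).

Two estimators are provided:

- `intron_inclusion_ratio()` — mean per-base coverage of I8 divided by
  the average of the flanking exon means (a `pooled` variant
  length-weights the exons); zero exon coverage yields `NA` flagged
  `undefined`, never infinity.
- `estimate_isoform_fractions()` — non-negative least squares of the
  observed segment coverages (pooled constitutive exons, I5, I8) against
  the isoform inclusion matrix; the fraction vector is the renormalized
  solution and the overall depth its sum. The inclusion matrix is
  rank-checked first: sets that are not identifiable from coverage alone
  (e.g. adding the doubly retained `I5_I8` form) are rejected with advice
  to bring junction-read evidence.

The NNLS fit is verified in the tests against an exhaustive 0.01-step
simplex grid search with the depth profiled out analytically.

# Cohort statistics

`simulate_cohort()` plants per-fish conversion outcomes
(`Bernoulli(conversion_prob)`) across families and generates log2-scale
marker expression (dmrt1, cyp19a1a) separated by `marker_sep` between
phenotypes. The marker noise is Gaussian *truncated* at `marker_sep / 4`
so the marker classifier (`male` iff dmrt1 strictly exceeds cyp19a1a,
ties resolved female with a message) is always consistent with the
planted phenotype — the cohort statistics are then scored purely on the
binomial sampling of conversions, not on classifier error.
`reversal_ratio()` reports per-family proportions and a pooled estimate
with an exact Clopper–Pearson interval. `relative_expression()` supplies
the comparative-Ct (`2^-ddCt`) statistic with a beta-actin-role reference,
and `percent_reduction()` the headline reduction in phenotypic males
(e.g. 32.7% observed against a 100% baseline gives 67.3%).

# Localization

`cell_ratio()` offers both readings of the nuclear/cytoplasmic ratio:
`density` (each compartment's intensity divided by its own area) and
`dapi_area` (areas cancel, plain intensity ratio); they agree exactly
when the areas are equal. `group_mean_ratio()` averages over at least 20
usable cells (the per-image quota) and refuses smaller groups by name.
`synthetic_cell_image()` builds a ground-truthed disk-on-rectangle toy
image to exercise the extraction path.

# Problem sizes and verification

The acceptance checks run at: 10,000 null genes (type-I rate), 2000 genes
with 40 planted 4-fold effects at 50 replicates (effect recovery; the
planted fraction is kept to about 2% so normalization cannot absorb the
shift, mirroring the few-hundred-of-twenty-thousand scale of real
sex-biased gene sets), 200 genes for cluster recovery, 50 seeded runs of
the repressive-coupling integration, 20 noisy coverage simulations for
isoform recovery, and 180-fish cohorts for the reversal ratio. Every
estimator with a nontrivial algorithm is additionally checked against an
independent oracle: a scripted TMM formula, boolean-mask interval unions,
a quadratic overlap scan, an exhaustive taxonomy case table and the
simplex grid search.

# Limitations

- The DE test assumes a common dispersion per feature across groups and
  does not shrink dispersions across genes; it is calibrated for the
  simulated designs, not a general-purpose replacement for
  moderated-dispersion methods on real data.
- The integration screen correlates five group means; it ranks and
  triages, it does not test.
- The coverage-based isoform model is linear in segment means and blind
  to junction reads; isoform sets outside its identifiable family need
  junction evidence.
- The simulators emulate the statistical frame of the study (group
  structure, effect directions, marker separation), not the underlying
  biology or sequencing artifacts.
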