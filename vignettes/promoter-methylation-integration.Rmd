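---
title: "Methods: paired-cohort promoter methylation and expression integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-cohort promoter methylation and expression integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promethex)
```

This vignette is the package's own account of its models, its numerical
choices, and what its synthetic experiments do and do not demonstrate.

## The measurement model

An Infinium-style array reports, per CpG probe and sample, a methylated
intensity $m$ and an unmethylated intensity $u$ (either may be negative after
background correction). The methylation fraction is estimated as

$$\beta = \frac{\max(m,0)}{\max(u,0) + \max(m,0) + \alpha}, \qquad \alpha = 100,$$

which clips negative channels and shrinks low-intensity probes toward 0; for
$\alpha > 0$ the estimate is strictly below 1. The default $\alpha$ follows
the array manufacturer's recommendation and is configurable
(`pipeline_config(alpha = )`).

Probe-level exclusions applied before any testing:

* detection $p > 0.01$ — by default a probe failing in *any* sample of the
  analysis cohort is dropped entirely, matching a probe-level reading of the
  rule; per-sample masking is available
  (`detection_exclusions(scope = "per_sample")`). Whether real studies filter
  per cohort or across all samples is usually unstated; we filter over all
  samples entering the run.
* annotation-based masks: multi-mapping, repeat overlap, a polymorphic SNP
  (MAF > 0.01) within 10 bp of the interrogated cytosine, indel overlap, and
  sex-chromosome location. "Within 10 bp" is read inclusively
  ($|{\rm snp}-{\rm cpg}| \le 10$); both the window and the MAF floor are
  arguments of `snp_proximity_flag()`. Mask flags are consumed as precomputed
  annotation columns; running an aligner is out of scope. Positions are
  1-based points; BED input is converted from its 0-based half-open
  convention by `read_bed()`.

Two normalizations follow. The within-array step harmonizes the two Infinium
design chemistries in the spirit of subset-quantile normalization, but
operates directly on beta values: probes are stratified by CpG count (1, 2,
3+); within a stratum an equal-size random subset of each design type is
drawn, the mean of the two sorted subsets defines a reference distribution,
and each type is mapped onto it by linearly interpolated quantile mapping.
The published subset-quantile method works on raw Illumina intensities with
platform internals we do not model; the beta-level variant keeps the intent
(type I/II harmonization) with fully specified arithmetic, is a fixed point
when the two types already agree, and is deterministic given its seed.
Between samples we then apply classical full quantile normalization on beta
values — each sample's order statistics are replaced by the across-sample
mean of order statistics, ties receiving the mean of the reference values
they span, missing entries staying missing — run separately per array
platform (each platform is normalized over the probes it actually measures)
before the matrices are merged on the shared probe set.

## Differential methylation with split-sample replication

Per probe, tumor and normal beta values of the same patients are compared
with the paired Wilcoxon signed-rank test: zero differences dropped, average
ranks for ties, $W$ the positive-rank sum. For $n' \le 25$ the two-sided
p value is exact, from the full $2^{n'}$ sign-assignment null computed by a
dynamic program over the doubled ranks (so tied, half-integer ranks are
handled exactly); above that, a normal approximation with tie-corrected
variance and continuity correction. Benjamini–Hochberg correction is applied
over all probes of a subset, and significance additionally requires
$|\Delta\beta| \ge 0.2$, the direction being the sign of $\Delta\beta$.

The two-platform design gives two discovery subsets: probes shared by both
arrays, tested over all discovery patients at $q < 0.05$; and EPIC-exclusive
probes, tested over the EPIC discovery patients only at the stricter
$q < 0.02$. The subsets partition the tested probes. Validation re-tests
only the discovery-significant probes in the independent validation half,
with BH over exactly that set — correcting over the whole array at the
second stage would be anti-conservative bookkeeping for a two-stage design —
and requires the same $q < 0.05$ and $|\Delta\beta| \ge 0.2$ gates plus
direction consistency. Both choices (validation BH universe, direction
consistency) are configurable because published pipelines rarely state them;
the defaults are the stricter reading.

Validated probes are aggregated into differentially methylated regions: a
gene region (promoter, gene body, or 3'UTR) containing one or more
direction-consistent validated probes, quantified per sample as the
unweighted mean of member betas. "Promoter" covers TSS1500, TSS200, 5'UTR
and 1st exon — 1500 nt upstream of the TSS through the first exon. Regions
with mixed-direction members are excluded and counted (how such regions
should be handled is genuinely open; exclusion follows the definition of a
DMR as unidirectional, and `split_mixed = TRUE` offers the alternative). A
probe annotated to several genes contributes to each independently.

## Differential expression

Expression arrives as a gene × sample FPKM matrix; read alignment and FPKM
estimation are upstream of this package. Both stages use the paired t test
on $\log_2(\mathrm{FPKM}+1)$ — the test the validation stage of the original
design specifies — because the discovery-stage alternative (cuffdiff)
consumes read-level data. Significance requires BH $q < 0.05$ and mean
per-patient $|\log_2 \mathrm{FC}| > 1$ (at least two-fold), with the fold
change defined as the mean over patients of
$\log_2\frac{t_i + 1}{n_i + 1}$; the pseudocount stabilizes zeros and is
configurable. Zero-variance difference vectors are degenerate for the t
statistic; such genes are flagged and excluded from the correction. Exact
numerical parity with read-level discovery tools is not claimed.

## Integration

A gene is a candidate iff its promoter DMR and its expression change are
both validated; candidates must oppose (hyper with down, or hypo with up).
For each survivor, Spearman's $\rho$ is computed between the promoter
methylation level (mean beta over the union of the gene's validated promoter
probes) and FPKM, across the pooled tumor *and* normal samples of patients
carrying both assays; pooling spans the dynamic range the inverse relation
needs (a tumor-only mode exists, since which sample set published analyses
pool is typically unstated). The p value uses the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ (exact permutation enumeration available
for $n \le 8$); the test is two-sided with a post-hoc sign requirement
$\rho < 0$, matching "significant negative correlation" without switching to
a one-sided null. BH runs over the candidate set; retention requires
$q < 0.05$. Genes with fewer than 4 usable paired samples are excluded and
reported.

## Downstream analyses

*Clustering.* Patients are clustered on per-patient promoter
$\Delta\beta$ (tumor minus normal region beta) of the integrated genes,
with per-gene median imputation of missing entries, Euclidean distance, and
Ward linkage (`ward.D2`, the Euclidean-consistent Ward variant); labels come
from cutting at $k$ clusters (default 2). `hclust` is deterministic for a
given input order, which the fixed pipeline ordering guarantees.

*Enrichment.* Right-sided hypergeometric tests
($P(X \ge k)$ over a background of all genes present in both the annotation
and the expression matrix) with BH across the sets of one collection. The
background universe of published enrichment tools is generally tool-internal,
so printed enrichment p values of any particular study are not reproduction
targets; the arithmetic is verified against enumeration instead.

*Drug reversal.* An epigenetically downregulated gene matches interactions
that increase its expression; an upregulated gene, those that decrease it.
The join is over a supplied drug–gene–direction table; live database access
is out of scope.

## The synthetic cohort

`sim_config()` defines the study conditions; the defaults are the package's
reference scenario and are not adjusted per experiment:

* cohort layout 25 (450K) + 18 (EPIC) discovery and 44 (EPIC) validation
  methylation pairs; 36 + 36 expression pairs drawn from them — the sizes of
  the two-platform case series this design mirrors;
* 5000 probes, 500 genes; planted $|\Delta\beta| = 0.3$ on 5% (hyper) + 3%
  (hypo) of probes; 40 genes with promoter-coupled expression
  (slope $-2$ on the logit scale, log-noise sd 0.3) and 20 expression-only
  genes;
* normal-tissue beta drawn $\mathrm{Beta}(\mu\kappa, (1-\mu)\kappa)$ with
  $\kappa = 50$ and baseline $\mu$ set by CpG-island relation (islands 0.15
  up to open sea 0.75, with per-probe jitter) — array betas are classically
  Beta-like, and the concentration reproduces the narrow within-group spread
  of good-quality arrays;
* intensities derived as $m = \beta S$, $u = (1-\beta)S$ with a log-normal
  per-sample scale ($e^{\log 10^4 \pm 0.2}$, per-probe factor sd 0.1) —
  enough to exercise the $\alpha$ shrinkage without modelling dye chemistry;
* detection failures on $2\times10^{-4}$ of probe–sample pairs (drawn above
  the 0.01 threshold). How failed detections distribute in real data is not
  published; this rate is typical of high-quality runs and makes the
  any-sample filter drop a few percent of probes, as observed in practice.

Planting respects the masks and the Beta support: effects land on probes
that survive the static filters and whose baseline leaves headroom for the
$\pm\delta$ shift, with hypermethylation skewed to islands/shores and
hypomethylation to open sea/shelves — the direction–context association
tumor arrays actually show. Promoter probes of the designated coupled genes
are planted first, in that gene's direction only, and are excluded from the
random fill so their regions stay direction-pure. Truth (per-probe effect,
per-gene regulation class) is returned as a ledger for recovery scoring
(`assess_recovery()`).

What the generator does **not** emulate: batch and chip effects, cell-type
composition, dye bias, spatially correlated neighboring probes, count-level
expression noise, or annotation errors. Passing recovery tests therefore
demonstrates the pipeline's statistical logic under its own assumptions —
not robustness to the technical structure of real arrays.

## Numerical choices and degenerate inputs

* Seeds: one master seed fans out to fixed per-stage offsets, so stages are
  independently reproducible; all derived seeds stay below $2^{31}$.
* Wilcoxon: all-zero difference vectors give $p = 1$ with a warning; fewer
  than 2 pairs is an error.
* Spearman: constant input is flagged rather than returning $\rho = 0$;
  $|\rho| = 1$ short-circuits the t approximation to $p = 0$.
* Quantile normalization: samples with fewer observed values than the
  reference grid are mapped through interpolated quantiles; an all-missing
  sample is an error.
* Within-array normalization: a stratum with under two probes of either
  design type is skipped with a warning; a single design type is returned
  unchanged.
* Ties in `hclust` merges resolve by the algorithm's stable order; duplicate
  profiles merge at height zero first.

## Problem sizes used in the shipped experiments

The package's tests and the acceptance script run entirely on synthetic
data: the reference scenario above for recovery (one run, ~5 s), reduced
null cohorts (2000 probes, 10 + 10 discovery and 20 validation pairs; 100
replicates in the test suite, 30 in the acceptance script) for
false-validation calibration, and 50 replicates of a 40-gene
null candidate set for the correlation-stage false-retention rate. These
sizes give binomial standard errors comfortably inside the tolerances the
checks assert while keeping a full run in tens of seconds.

## Known limitations

* The two normalizations are the only batch handling; no NOOB-style
  background correction, cell-composition adjustment, or covariate models.
* DMRs are annotation-region aggregates; no sliding-window or bump-hunting
  region detection.
* Integration is correlational; no mediation or causal claims.
* The discovery-stage DE test deviates from read-level tools by design (see
  above).
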