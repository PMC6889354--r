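Package: promethex
Title: Integrative Promoter Methylation and Expression Analysis of Paired
    Tumor-Normal Cohorts
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for integrative epigenome-transcriptome analysis of paired
    tumor-normal cohorts profiled on Infinium-style methylation arrays and
    RNA-seq (FPKM). Converts raw methylated/unmethylated intensities to beta
    values with offset shrinkage, applies probe-level exclusion rules
    (detection p, multi-mapping, repeats, SNP proximity, indels, sex
    chromosomes), performs within-array (type I/II subset-quantile) and
    between-sample quantile normalization, calls differentially methylated
    probes with paired Wilcoxon signed-rank tests under a discovery/validation
    replication design, aggregates unidirectional probes into gene-region
    methylation scores, calls paired differential expression, and retains
    genes whose promoter methylation is significantly inversely correlated
    (Spearman) with expression. Downstream utilities provide Ward clustering
    of per-patient methylation changes, cluster-phenotype cross-tabulation,
    right-sided hypergeometric gene-set enrichment, and drug-reversal
    candidate lookup. A fully parameterized synthetic-cohort generator with
    planted effects supports power, calibration, and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    mclust
Config/testthat/edition: 3
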