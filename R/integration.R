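#' Genes significant in both promoter methylation and expression
#'
#' Intersects the genes carrying a validated promoter DMR with the validated
#' differentially expressed genes; body- or 3'UTR-only DMR genes are not
#' candidates.
#'
#' @param dmrs DMR data frame from [build_dmrs()].
#' @param de_calls Validated DE table from [validate_de()].
#' @return Data frame: `gene_id`, `methylation_direction`,
#'   `expression_direction`.
#' @export
select_candidates <- function(dmrs, de_calls) {
  prom <- dmrs[dmrs$region_class == "promoter", , drop = FALSE]
  de <- de_calls[de_calls$validated, , drop = FALSE]
  genes <- intersect(prom$gene_id, de$gene_id)
  data.frame(
    gene_id = genes,
    methylation_direction = prom$direction[match(genes, prom$gene_id)],
    expression_direction = de$direction[match(genes, de$gene_id)],
    stringsAsFactors = FALSE)
}

#' Opposite-direction filter
#'
#' Keeps genes whose promoter methylation and expression move in opposite
#' directions: promoter hypermethylation with underexpression
#' (`epigenetically_downregulated`) or hypomethylation with overexpression
#' (`epigenetically_upregulated`). Concordant genes are discarded and
#' counted in the `n_discarded` attribute.
#'
#' @param candidates Output of [select_candidates()].
#' @return Filtered data frame with an added `regulation_class` column.
#' @export
direction_filter <- function(candidates) {
  keep_down <- candidates$methylation_direction == "hyper" &
    candidates$expression_direction == "down"
  keep_up <- candidates$methylation_direction == "hypo" &
    candidates$expression_direction == "up"
  out <- candidates[keep_down | keep_up, , drop = FALSE]
  out$regulation_class <- ifelse(
    out$methylation_direction == "hyper",
    "epigenetically_downregulated", "epigenetically_upregulated")
  rownames(out) <- NULL
  attr(out, "n_discarded") <- sum(!(keep_down | keep_up))
  out
}

#' Spearman correlation gate and final integrated gene list
#'
#' For each direction-filtered candidate gene, the promoter methylation
#' level (per-sample mean beta over the union of its validated promoter
#' DMPs) is correlated (Spearman) with FPKM across the pooled tumor and
#' normal samples of patients carrying both assays (`samples =
#' "tumor_only"` restricts to tumors). BH correction is applied over the
#' candidate set; a gene is retained iff `rho < 0` and adjusted p <
#' `q_threshold`. Genes with fewer than `min_n` usable paired samples are
#' excluded and reported.
#'
#' @param filtered Output of [direction_filter()].
#' @param region_beta Region-beta matrix from [build_dmrs()] (rows keyed
#'   `"gene|region_class"`).
#' @param fpkm Genes x samples FPKM matrix.
#' @param design Cohort design (used to pool tumor/normal expression
#'   samples).
#' @param q_threshold Adjusted-p cutoff (default 0.05).
#' @param samples `"pooled"` (default) or `"tumor_only"`.
#' @param min_n Minimum usable samples per gene (default 4).
#' @return Data frame: `gene_id`, directions, `regulation_class`, `rho`,
#'   `n_samples`, `p_raw`, `p_adj`, `retained`; genes lacking data in the
#'   `excluded_genes` attribute.
#' @export
correlate_and_finalize <- function(filtered, region_beta, fpkm, design,
                                   q_threshold = 0.05,
                                   samples = c("pooled", "tumor_only"),
                                   min_n = 4L) {
  samples <- match.arg(samples)
  des <- design[design$expr_cohort != "none", , drop = FALSE]
  ids <- if (samples == "pooled")
    c(des$tumor_sample_id, des$normal_sample_id)
  else des$tumor_sample_id
  ids <- intersect(ids, intersect(colnames(region_beta), colnames(fpkm)))
  out <- filtered
  out$rho <- rep(NA_real_, nrow(out))
  out$n_samples <- rep(NA_integer_, nrow(out))
  out$p_raw <- rep(NA_real_, nrow(out))
  excluded <- character(0)
  for (i in seq_len(nrow(out))) {
    g <- out$gene_id[i]
    key <- paste(g, "promoter", sep = "|")
    if (!key %in% rownames(region_beta) || !g %in% rownames(fpkm)) {
      excluded <- c(excluded, g); next
    }
    x <- region_beta[key, ids]
    y <- fpkm[g, ids]
    ok <- !(is.na(x) | is.na(y))
    if (sum(ok) < min_n) { excluded <- c(excluded, g); next }
    st <- spearman_test(x[ok], y[ok])
    out$rho[i] <- st$rho
    out$n_samples[i] <- st$n
    out$p_raw[i] <- st$p_value
  }
  out <- out[!out$gene_id %in% excluded, , drop = FALSE]
  out$p_adj <- bh_adjust(out$p_raw)
  out$retained <- !is.na(out$rho) & out$rho < 0 &
    !is.na(out$p_adj) & out$p_adj < q_threshold
  rownames(out) <- NULL
  attr(out, "excluded_genes") <- excluded
  out
}

#' Full integration stage
#'
#' Convenience wrapper chaining [select_candidates()], [direction_filter()]
#' and [correlate_and_finalize()].
#'
#' @inheritParams correlate_and_finalize
#' @param dmrs,de_calls As in [select_candidates()].
#' @return The finalized integrated-gene table (see
#'   [correlate_and_finalize()]); candidate/discard bookkeeping in
#'   attributes `n_candidates` and `n_discarded_concordant`.
#' @export
integrate_methylation_expression <- function(dmrs, de_calls, region_beta,
                                             fpkm, design, q_threshold = 0.05,
                                             samples = "pooled", min_n = 4L) {
  cand <- select_candidates(dmrs, de_calls)
  filt <- direction_filter(cand)
  out <- correlate_and_finalize(filt, region_beta, fpkm, design,
                                q_threshold = q_threshold, samples = samples,
                                min_n = min_n)
  attr(out, "n_candidates") <- nrow(cand)
  attr(out, "n_discarded_concordant") <- attr(filt, "n_discarded")
  out
}
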