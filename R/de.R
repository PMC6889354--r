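#' Per-patient log2 fold change
#'
#' `log2((tumor + pseudocount) / (normal + pseudocount))` per patient; the
#' gene-level effect size is the mean of these per-patient values.
#'
#' @param tumor_fpkm,normal_fpkm Non-negative paired FPKM vectors.
#' @param pseudocount Positive stabilizer (default 1).
#' @return Per-patient log2 fold changes.
#' @examples
#' per_patient_log2fc(8, 2) # log2(9/3) = 1.585
#' @export
per_patient_log2fc <- function(tumor_fpkm, normal_fpkm, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (any(tumor_fpkm < 0, na.rm = TRUE) || any(normal_fpkm < 0, na.rm = TRUE))
    stop("validation error: FPKM must be non-negative")
  log2((tumor_fpkm + pseudocount) / (normal_fpkm + pseudocount))
}

# Vectorized paired t over rows of log2(FPKM + pseudocount) matrices.
#' @noRd
.row_paired_t <- function(tum, nor) {
  d <- tum - nor
  n <- rowSums(!is.na(d))
  mean_d <- rowMeans(d, na.rm = TRUE)
  sd_d <- apply(d, 1L, stats::sd, na.rm = TRUE)
  tstat <- ifelse(sd_d > 0 & n >= 3, mean_d / (sd_d / sqrt(n)), NA_real_)
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  list(statistic = tstat, p_value = p, mean_log2fc = mean_d, n = n,
       degenerate = sd_d == 0)
}

#' Call differentially expressed genes in a cohort
#'
#' Per gene, a paired t test on `log2(FPKM + pseudocount)` compares tumor and
#' normal samples of the cohort's patients, with BH correction over all genes
#' tested. A gene is significant iff adjusted p < `q_threshold` AND the mean
#' per-patient `|log2 fold change| > min_abs_log2fc` (at the defaults, at
#' least two-fold). Genes with zero-variance differences are degenerate: the
#' p value is `NA` and they are excluded from the correction.
#'
#' @param fpkm Genes x samples FPKM matrix.
#' @param design Cohort design with `expr_cohort`, `tumor_sample_id`,
#'   `normal_sample_id`.
#' @param cohort `"discovery"` (default) or `"validation"`.
#' @param q_threshold BH-adjusted p cutoff (default 0.05).
#' @param min_abs_log2fc Fold-change cutoff (default 1).
#' @param pseudocount Pseudocount for the log transform (default 1).
#' @return Data frame: `gene_id`, `n_pairs`, `mean_log2fc`, `statistic`,
#'   `p_raw`, `p_adj`, `direction` (`up`/`down` by the sign of the fold
#'   change), `degenerate`, `significant`.
#' @export
call_de <- function(fpkm, design, cohort = "discovery", q_threshold = 0.05,
                    min_abs_log2fc = 1, pseudocount = 1) {
  des <- design[design$expr_cohort == cohort, , drop = FALSE]
  if (nrow(des) < 3L) stop("fewer than 3 ", cohort, " expression patients")
  if (any(fpkm < 0, na.rm = TRUE)) stop("validation error: FPKM must be non-negative")
  L <- log2(fpkm + pseudocount)
  res <- .row_paired_t(L[, des$tumor_sample_id, drop = FALSE],
                       L[, des$normal_sample_id, drop = FALSE])
  p_adj <- bh_adjust(res$p_value)
  data.frame(gene_id = rownames(fpkm), n_pairs = res$n,
             mean_log2fc = unname(res$mean_log2fc),
             statistic = unname(res$statistic),
             p_raw = unname(res$p_value), p_adj = unname(p_adj),
             direction = ifelse(res$mean_log2fc > 0, "up", "down"),
             degenerate = unname(res$degenerate),
             significant = !is.na(p_adj) & p_adj < q_threshold &
               abs(res$mean_log2fc) > min_abs_log2fc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Validate discovery DE calls in the validation cohort
#'
#' The same paired t test is applied to the validation cohort, restricted to
#' the discovery-significant genes, with BH correction over that set; a gene
#' is validated iff it passes the same adjusted-p and fold-change thresholds
#' with direction consistent with discovery. Genes absent from the validation
#' matrix are excluded and reported.
#'
#' @param discovery_calls Output of [call_de()].
#' @param fpkm,design Validation-cohort inputs.
#' @param q_threshold,min_abs_log2fc,pseudocount As in [call_de()].
#' @return Discovery table augmented with `validation_*` columns and
#'   `validated`; excluded genes in the `excluded_genes` attribute.
#' @export
validate_de <- function(discovery_calls, fpkm, design, q_threshold = 0.05,
                        min_abs_log2fc = 1, pseudocount = 1) {
  out <- discovery_calls
  out$validation_mean_log2fc <- NA_real_
  out$validation_p_raw <- NA_real_
  out$validation_p_adj <- NA_real_
  out$validated <- FALSE
  sig <- discovery_calls$gene_id[discovery_calls$significant]
  present <- sig[sig %in% rownames(fpkm)]
  attr(out, "excluded_genes") <- setdiff(sig, present)
  if (length(present) == 0L) return(out)
  val <- call_de(fpkm[present, , drop = FALSE], design, cohort = "validation",
                 q_threshold = q_threshold, min_abs_log2fc = min_abs_log2fc,
                 pseudocount = pseudocount)
  i <- match(present, out$gene_id)
  out$validation_mean_log2fc[i] <- val$mean_log2fc
  out$validation_p_raw[i] <- val$p_raw
  out$validation_p_adj[i] <- val$p_adj
  out$validated[i] <- val$significant & val$direction == out$direction[i]
  out
}
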