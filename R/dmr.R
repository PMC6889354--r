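#' Probe to gene-region mapping with promoter classification
#'
#' Expands the annotation's `gene_regions` strings into one row per
#' (probe, gene, region) assignment and classifies each as `promoter`
#' (TSS1500, TSS200, 5'UTR or 1st exon -- i.e. 1500 nt upstream of the TSS
#' through the first exon), `body`, or `3UTR`. A probe serving several genes
#' contributes one row per gene, counted independently.
#'
#' @param annotation Probe annotation with `probe_id` and `gene_regions`.
#' @return Data frame with `probe_id`, `gene_id`, `region`, `region_class`.
#' @export
assign_promoter <- function(annotation) {
  has <- annotation$gene_regions != "" & !is.na(annotation$gene_regions)
  if (!any(has))
    return(data.frame(probe_id = character(0), gene_id = character(0),
                      region = character(0), region_class = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(annotation$gene_regions[has], ";", fixed = TRUE)
  n_each <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  gi <- sub(":.*$", "", flat)
  reg <- sub("^[^:]*:", "", flat)
  bad <- !reg %in% c(.promoter_regions, "body", "3UTR")
  if (any(bad)) stop("unknown gene-region label(s): ",
                     paste(unique(reg[bad]), collapse = ", "))
  data.frame(
    probe_id = rep(annotation$probe_id[has], n_each),
    gene_id = gi, region = reg,
    region_class = ifelse(reg %in% .promoter_regions, "promoter",
                          ifelse(reg == "body", "body", "3UTR")),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Build differentially methylated regions from validated DMPs
#'
#' A DMR is a gene region (promoter, body or 3'UTR of one gene) containing
#' one or more direction-consistent validated DMPs; its per-sample
#' methylation level is the unweighted mean of the member probes' beta
#' values. Regions whose member DMPs disagree in direction are excluded by
#' default and counted (set `split_mixed = TRUE` to instead emit one
#' direction-pure DMR per direction, for sensitivity analysis).
#'
#' @param validated_calls DMP table with a logical `validated` column (or
#'   any table whose rows are all taken as validated DMPs with `probe_id`
#'   and `direction`).
#' @param mapping Probe-region mapping from [assign_promoter()].
#' @param beta Probes x samples beta matrix for region quantification.
#' @param split_mixed Emit direction-split DMRs for mixed regions.
#' @return List with `dmrs` (data frame: `gene_id`, `region_class`,
#'   `direction`, `n_probes`, `probe_ids`), `region_beta` (matrix, rows
#'   keyed `"gene|region_class"`, or `"gene|region_class|direction"` when
#'   split), and `n_mixed_excluded`.
#' @export
build_dmrs <- function(validated_calls, mapping, beta, split_mixed = FALSE) {
  calls <- validated_calls
  if ("validated" %in% names(calls)) calls <- calls[calls$validated, , drop = FALSE]
  calls <- calls[!is.na(calls$direction), , drop = FALSE]
  empty <- list(dmrs = data.frame(gene_id = character(0),
                                  region_class = character(0),
                                  direction = character(0),
                                  n_probes = integer(0),
                                  probe_ids = character(0),
                                  stringsAsFactors = FALSE),
                region_beta = matrix(numeric(0), 0, ncol(beta),
                                     dimnames = list(NULL, colnames(beta))),
                n_mixed_excluded = 0L)
  if (nrow(calls) == 0L) return(empty)
  hits <- mapping[mapping$probe_id %in% calls$probe_id, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  hits$direction <- calls$direction[match(hits$probe_id, calls$probe_id)]
  key <- paste(hits$gene_id, hits$region_class, sep = "|")
  groups <- split(hits, key)
  # sort members so the record never depends on probe input order
  rows <- list(); beta_rows <- list(); n_mixed <- 0L
  for (k in sort(names(groups))) {
    g <- groups[[k]]
    dirs <- sort(unique(g$direction))
    if (length(dirs) > 1L && !split_mixed) { n_mixed <- n_mixed + 1L; next }
    for (d in dirs) {
      pid <- sort(unique(g$probe_id[g$direction == d]))
      pid <- pid[pid %in% rownames(beta)]
      if (length(pid) == 0L) next
      rb <- colMeans(beta[pid, , drop = FALSE], na.rm = TRUE)
      rb[is.nan(rb)] <- NA_real_
      rkey <- if (length(dirs) > 1L) paste(k, d, sep = "|") else k
      rows[[rkey]] <- data.frame(gene_id = g$gene_id[1L],
                                 region_class = g$region_class[1L],
                                 direction = d, n_probes = length(pid),
                                 probe_ids = paste(pid, collapse = ";"),
                                 stringsAsFactors = FALSE)
      beta_rows[[rkey]] <- rb
    }
  }
  if (length(rows) == 0L) {
    empty$n_mixed_excluded <- n_mixed
    return(empty)
  }
  dmrs <- do.call(rbind, rows)
  region_beta <- do.call(rbind, beta_rows)
  rownames(region_beta) <- names(beta_rows)
  dmrs <- cbind(region_key = names(rows), dmrs,
                stringsAsFactors = FALSE)
  rownames(dmrs) <- NULL
  list(dmrs = dmrs, region_beta = region_beta, n_mixed_excluded = n_mixed)
}

#' Summarize DMR counts by gene region
#'
#' Counts genes with promoter DMRs split by direction, and the share of all
#' DMRs that are promoters.
#'
#' @param dmrs The `dmrs` data frame from [build_dmrs()].
#' @return List with `n_promoter_genes`, `n_promoter_hyper`,
#'   `n_promoter_hypo`, `n_gene_regions`, `pct_promoter`.
#' @export
count_region_genes <- function(dmrs) {
  prom <- dmrs[dmrs$region_class == "promoter", , drop = FALSE]
  n_regions <- nrow(dmrs)
  list(n_promoter_genes = length(unique(prom$gene_id)),
       n_promoter_hyper = length(unique(prom$gene_id[prom$direction == "hyper"])),
       n_promoter_hypo = length(unique(prom$gene_id[prom$direction == "hypo"])),
       n_gene_regions = n_regions,
       pct_promoter = if (n_regions) percent(nrow(prom), n_regions, 1) else NA_real_)
}
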