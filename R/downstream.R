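#' Per-patient promoter methylation change matrix
#'
#' `delta_beta(patient, gene) = tumor region beta - normal region beta` for
#' each integrated gene, over patients with both samples; a missing member of
#' the pair leaves that entry `NA`.
#'
#' @param genes Character vector of gene ids (rows keyed
#'   `"gene|promoter"` must exist in `region_beta`).
#' @param region_beta Region-beta matrix from [build_dmrs()].
#' @param design Cohort design.
#' @return Patients x genes matrix of delta beta values.
#' @export
patient_delta_beta <- function(genes, region_beta, design) {
  keys <- paste(genes, "promoter", sep = "|")
  miss <- genes[!keys %in% rownames(region_beta)]
  if (length(miss)) stop("no promoter region beta for gene(s): ",
                         paste(miss, collapse = ", "))
  des <- design[design$tumor_sample_id %in% colnames(region_beta) &
                  design$normal_sample_id %in% colnames(region_beta), ,
                drop = FALSE]
  tum <- t(region_beta[keys, des$tumor_sample_id, drop = FALSE])
  nor <- t(region_beta[keys, des$normal_sample_id, drop = FALSE])
  out <- tum - nor
  dimnames(out) <- list(des$patient_id, genes)
  out
}

#' Ward clustering of patients on methylation change
#'
#' Agglomerative hierarchical clustering with Ward linkage (`ward.D2`) on
#' Euclidean distances between patient delta-beta profiles; missing entries
#' are imputed by the per-gene median before distances are computed. Labels
#' come from cutting the tree at `k` clusters. Deterministic for a given
#' input order.
#'
#' @param delta_matrix Patients x genes matrix from [patient_delta_beta()].
#' @param k Number of clusters (default 2; must not exceed the patient
#'   count).
#' @return List with `hclust` (the dendrogram) and `labels` (named integer
#'   cluster assignment).
#' @export
ward_cluster <- function(delta_matrix, k = 2L) {
  n <- nrow(delta_matrix)
  if (n < 3L) stop("need at least 3 patients")
  if (k > n) stop("k must not exceed the number of patients")
  x <- delta_matrix
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- stats::median(x[, j], na.rm = TRUE)
  }
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  list(hclust = hc, labels = labels)
}

#' Cluster-phenotype cross-tabulation
#'
#' Per cluster, counts and proportions of patients at higher tumor stage
#' (T3/T4) and with nodal involvement (N+); missing clinical values are
#' tabulated as `unknown` and excluded from the denominators.
#'
#' @param labels Named cluster labels from [ward_cluster()].
#' @param design Cohort design with `patient_id`, `T_stage`, `N_stage`.
#' @return Data frame with one row per cluster.
#' @export
cluster_phenotype_table <- function(labels, design) {
  des <- design[match(names(labels), design$patient_id), , drop = FALSE]
  do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    i <- labels == cl
    t_known <- !is.na(des$T_stage[i]); n_known <- !is.na(des$N_stage[i])
    high_t <- des$T_stage[i] %in% c("T3", "T4")
    n_pos <- des$N_stage[i] %in% "N+"
    data.frame(
      cluster = cl, n_patients = sum(i),
      n_T34 = sum(high_t), n_T_unknown = sum(!t_known),
      pct_T34 = if (any(t_known)) percent(sum(high_t), sum(t_known)) else NA_real_,
      n_Npos = sum(n_pos), n_N_unknown = sum(!n_known),
      pct_Npos = if (any(n_known)) percent(sum(n_pos), sum(n_known)) else NA_real_,
      row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Right-sided hypergeometric gene-set enrichment
#'
#' For each set, `p = P(X >= k)` with X ~ Hypergeometric(background, set
#' size, query size) and k the observed overlap; BH correction across the
#' sets of the collection. The percent-associated column is
#' `100 * overlap / set size`.
#'
#' @param query Character vector of query genes (must lie in `background`).
#' @param gene_sets Named list of member vectors; members outside the
#'   background are dropped from the set before testing.
#' @param background Character vector: the gene universe.
#' @return Data frame sorted by p: `set_id`, `set_size`, `n_overlap`,
#'   `percent_associated`, `p_raw`, `p_adj`.
#' @export
hypergeometric_enrichment <- function(query, gene_sets, background) {
  query <- unique(query)
  if (!all(query %in% background))
    stop("validation error: query gene(s) outside the background: ",
         paste(utils::head(setdiff(query, background), 5L), collapse = ", "))
  N <- length(unique(background))
  n <- length(query)
  rows <- lapply(names(gene_sets), function(s) {
    members <- unique(intersect(gene_sets[[s]], background))
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, query))
    data.frame(set_id = s, set_size = K, n_overlap = k,
               percent_associated = percent(k, K, 2),
               p_raw = hypergeom_upper_tail(k, N, K, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set_id = character(0), set_size = integer(0),
                      n_overlap = integer(0), percent_associated = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0)))
  out$p_adj <- bh_adjust(out$p_raw)
  out <- out[order(out$p_raw, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drugs reversing epigenetic dysregulation
#'
#' An epigenetically downregulated gene matches drugs that increase its
#' expression; an epigenetically upregulated gene matches drugs that
#' decrease it. Same-direction interactions never match.
#'
#' @param integrated Integrated-gene table (rows with `retained == TRUE`
#'   are used if the column is present) with `gene_id` and
#'   `regulation_class`.
#' @param interactions Drug table with `drug`, `gene_id`, `effect`.
#' @return List with `matches` (data frame: `gene_id`, `regulation_class`,
#'   `drug`, `effect`) and `counts` (reversible genes by class).
#' @export
drug_reversal <- function(integrated, interactions) {
  genes <- integrated
  if ("retained" %in% names(genes)) genes <- genes[genes$retained, , drop = FALSE]
  wanted <- ifelse(genes$regulation_class == "epigenetically_downregulated",
                   "increases_expression", "decreases_expression")
  hit <- merge(
    data.frame(gene_id = genes$gene_id,
               regulation_class = genes$regulation_class,
               effect = wanted, stringsAsFactors = FALSE),
    interactions, by = c("gene_id", "effect"))
  hit <- hit[order(hit$gene_id, hit$drug), c("gene_id", "regulation_class",
                                             "drug", "effect")]
  rownames(hit) <- NULL
  counts <- c(
    n_reversible_down = length(unique(
      hit$gene_id[hit$regulation_class == "epigenetically_downregulated"])),
    n_reversible_up = length(unique(
      hit$gene_id[hit$regulation_class == "epigenetically_upregulated"])))
  list(matches = hit, counts = counts)
}
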