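#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis chain together with the
#' synthetic-cohort configuration. Round-trips losslessly through JSON (see
#' [write_pipeline_config()]).
#'
#' @param sim A [sim_config()] describing the cohort to simulate (or whose
#'   seed governs preprocessing randomness when data are supplied).
#' @param alpha Beta-value offset (default 100).
#' @param detection_p Detection failure threshold (default 0.01).
#' @param p_merged,p_epic Discovery adjusted-p cutoffs (0.05 / 0.02).
#' @param p_validation Validation adjusted-p cutoff (0.05).
#' @param min_delta Minimum absolute delta beta (0.2).
#' @param min_abs_log2fc Fold-change cutoff (1).
#' @param q_de,q_rho Adjusted-p cutoffs for expression and correlation
#'   stages (0.05 each).
#' @param k_clusters Clusters to cut the Ward tree at (2).
#' @return List of class `promethex_config`.
#' @export
pipeline_config <- function(sim = sim_config(), alpha = 100,
                            detection_p = 0.01, p_merged = 0.05,
                            p_epic = 0.02, p_validation = 0.05,
                            min_delta = 0.2, min_abs_log2fc = 1,
                            q_de = 0.05, q_rho = 0.05, k_clusters = 2L) {
  stopifnot(inherits(sim, "promethex_sim_config"))
  for (v in c(detection_p, p_merged, p_epic, p_validation, q_de, q_rho))
    .check_prob(v, "threshold")
  if (alpha < 0) .cfg_stop("alpha must be non-negative")
  if (min_delta < 0 || min_delta > 1) .cfg_stop("min_delta must lie in [0, 1]")
  if (min_abs_log2fc < 0) .cfg_stop("min_abs_log2fc must be non-negative")
  structure(list(sim = sim, alpha = alpha, detection_p = detection_p,
                 p_merged = p_merged, p_epic = p_epic,
                 p_validation = p_validation, min_delta = min_delta,
                 min_abs_log2fc = min_abs_log2fc, q_de = q_de, q_rho = q_rho,
                 k_clusters = as.integer(k_clusters)),
            class = "promethex_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `write_pipeline_config` the path, invisibly;
#'   `read_pipeline_config` the restored config.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "promethex_config"))
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- do.call(sim_config, x$sim)
  x$sim <- NULL
  do.call(pipeline_config, c(list(sim = sim), x))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> preprocess -> DMP discovery (merged + EPIC-only) ->
#' validation -> DMR aggregation -> DE discovery/validation -> inverse-
#' correlation integration -> downstream (patient clustering, phenotype
#' cross-tab, gene-set enrichment, drug reversal), writing every stage's
#' table plus a JSON run manifest to `out_dir` when given. Reruns with an
#' identical configuration are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for the result tables.
#' @param sim Optionally, a pre-built [simulate_cohort()] object matching
#'   `config$sim` (to reuse one simulation across analyses).
#' @param write_inputs Also write the simulated input tables (default
#'   FALSE).
#' @return Object of class `promethex_run` holding all stage outputs.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         sim = NULL, write_inputs = FALSE) {
  stopifnot(inherits(config, "promethex_config"))
  sim <- sim %||% simulate_cohort(config$sim)
  stopifnot(inherits(sim, "promethex_sim"))
  design <- sim$design

  platform_by_sample <- rep(design$platform, each = 2L)
  pre <- preprocess_cohort(sim$m, sim$u, sim$detection, sim$annotation,
                           platform = platform_by_sample,
                           alpha = config$alpha,
                           detection_threshold = config$detection_p,
                           seed = .stage_seed(config$sim$seed, "preprocess"))
  beta <- pre$beta

  dmp_merged <- call_dmps(beta, design, sim$annotation, "merged",
                          q_threshold = config$p_merged,
                          min_delta = config$min_delta)
  dmp_epic <- tryCatch(
    call_dmps(beta, design, sim$annotation, "epic_only",
              q_threshold = config$p_epic, min_delta = config$min_delta),
    error = function(e) NULL)
  discovery <- rbind(dmp_merged, dmp_epic)
  dmps <- validate_dmps(discovery, beta, design,
                        q_threshold = config$p_validation,
                        min_delta = config$min_delta)
  context <- summarize_dmp_context(dmps[dmps$validated, , drop = FALSE],
                                   sim$annotation)

  mapping <- assign_promoter(sim$annotation)
  dmr <- build_dmrs(dmps, mapping, beta)
  region_counts <- count_region_genes(dmr$dmrs)

  de_disc <- call_de(sim$fpkm, design, cohort = "discovery",
                     q_threshold = config$q_de,
                     min_abs_log2fc = config$min_abs_log2fc)
  de <- validate_de(de_disc, sim$fpkm, design, q_threshold = config$q_de,
                    min_abs_log2fc = config$min_abs_log2fc)

  integrated <- integrate_methylation_expression(
    dmr$dmrs, de, dmr$region_beta, sim$fpkm, design,
    q_threshold = config$q_rho)
  retained <- integrated[integrated$retained, , drop = FALSE]

  clusters <- NULL; crosstab <- NULL; delta_matrix <- NULL
  if (nrow(retained) >= 1L) {
    delta_matrix <- patient_delta_beta(retained$gene_id, dmr$region_beta,
                                       design)
    complete <- rowSums(!is.na(delta_matrix)) > 0L
    if (sum(complete) >= 3L) {
      clusters <- ward_cluster(delta_matrix[complete, , drop = FALSE],
                               k = min(config$k_clusters, sum(complete)))
      crosstab <- cluster_phenotype_table(clusters$labels, design)
    }
  }
  # enrichment background: genes present in both annotation and FPKM matrix
  background <- intersect(unique(mapping$gene_id), rownames(sim$fpkm))
  enrichment <- hypergeometric_enrichment(
    intersect(retained$gene_id, background), sim$gene_sets, background)
  reversal <- drug_reversal(retained, sim$drug_table)

  manifest <- list(
    package_version = as.character(utils::packageVersion("promethex")),
    seed = config$sim$seed,
    thresholds = unclass(config)[setdiff(names(unclass(config)), "sim")],
    counts = list(
      probes_simulated = nrow(sim$annotation),
      probes_kept = length(pre$kept_probes),
      probes_removed = unname(pre$attrition["input"] - pre$attrition["kept"]),
      dmps_tested = nrow(discovery),
      dmps_discovery_significant = sum(discovery$significant),
      dmps_validated = sum(dmps$validated),
      gene_regions = nrow(dmr$dmrs),
      mixed_regions_excluded = dmr$n_mixed_excluded,
      promoter_genes = region_counts$n_promoter_genes,
      de_tested = nrow(de),
      de_discovery_significant = sum(de$significant),
      de_validated = sum(de$validated),
      integration_candidates = attr(integrated, "n_candidates"),
      integration_concordant_discarded = attr(integrated, "n_discarded_concordant"),
      integrated_genes = nrow(retained),
      reversible_genes = sum(reversal$counts)))

  run <- structure(list(config = config, sim = sim, beta = beta,
                        attrition = pre$attrition, dmps = dmps,
                        context = context, dmr = dmr,
                        region_counts = region_counts, de = de,
                        integrated = integrated, delta_matrix = delta_matrix,
                        clusters = clusters, crosstab = crosstab,
                        enrichment = enrichment, reversal = reversal,
                        manifest = manifest),
                   class = "promethex_run")
  if (!is.null(out_dir)) .write_run(run, out_dir, write_inputs)
  run
}

#' @noRd
.write_run <- function(run, out_dir, write_inputs = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (write_inputs) write_cohort(run$sim, file.path(out_dir, "inputs"))
  write_matrix_tsv(run$beta, file.path(out_dir, "beta.tsv"), "probe_id")
  write_tsv(run$dmps, file.path(out_dir, "dmp_calls.tsv"))
  write_tsv(run$context$chromosome, file.path(out_dir, "context_chromosome.tsv"))
  write_tsv(run$context$cgi, file.path(out_dir, "context_cgi.tsv"))
  write_tsv(run$dmr$dmrs, file.path(out_dir, "dmr_calls.tsv"))
  if (nrow(run$dmr$region_beta))
    write_matrix_tsv(run$dmr$region_beta, file.path(out_dir, "region_beta.tsv"),
                     "region_key")
  write_tsv(run$de, file.path(out_dir, "de_calls.tsv"))
  write_tsv(run$integrated, file.path(out_dir, "integrated_genes.tsv"))
  if (!is.null(run$clusters))
    write_tsv(data.frame(patient_id = names(run$clusters$labels),
                         cluster = unname(run$clusters$labels)),
              file.path(out_dir, "clusters.tsv"))
  if (!is.null(run$crosstab))
    write_tsv(run$crosstab, file.path(out_dir, "phenotype_crosstab.tsv"))
  write_tsv(run$enrichment, file.path(out_dir, "enrichment.tsv"))
  write_tsv(run$reversal$matches, file.path(out_dir, "drug_reversal.tsv"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Compare pipeline calls with the planted truth
#'
#' Computes recovery metrics against the generator's truth ledger: DMP
#' sensitivity (validated among planted probes), the false-positive probe
#' rate (validated among null probes), and integrated-gene sensitivity
#' (retained among planted epigenetically regulated genes) with the null
#' gene retention rate.
#'
#' @param run A [run_pipeline()] result.
#' @return Named list of rates (proportions in `[0, 1]`) and counts.
#' @export
assess_recovery <- function(run) {
  stopifnot(inherits(run, "promethex_run"))
  truth <- run$sim$truth
  planted <- truth$probe_effects$probe_id[truth$probe_effects$effect != "null"]
  nulls <- truth$probe_effects$probe_id[truth$probe_effects$effect == "null"]
  called <- run$dmps$probe_id[run$dmps$validated]
  eg <- truth$gene_regulation$gene_id[
    truth$gene_regulation$class %in% c("epigenetically_down", "epigenetically_up")]
  null_genes <- truth$gene_regulation$gene_id[truth$gene_regulation$class == "null"]
  retained <- run$integrated$gene_id[run$integrated$retained]
  list(dmp_sensitivity = mean(planted %in% called),
       dmp_false_positive_rate = mean(nulls %in% called),
       integrated_sensitivity = mean(eg %in% retained),
       integrated_null_retention = mean(null_genes %in% retained),
       n_planted_probes = length(planted),
       n_validated_dmps = length(called),
       n_planted_genes = length(eg),
       n_integrated_genes = length(retained))
}

#' @export
print.promethex_run <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("promethex pipeline run (seed ", x$config$sim$seed, ")\n", sep = "")
  cat(sprintf("  probes: %d simulated, %d kept after filters\n",
              cnt$probes_simulated, cnt$probes_kept))
  cat(sprintf("  DMPs: %d tested, %d discovery-significant, %d validated\n",
              cnt$dmps_tested, cnt$dmps_discovery_significant,
              cnt$dmps_validated))
  cat(sprintf("  DMRs: %d gene regions (%d promoter genes; %d mixed excluded)\n",
              cnt$gene_regions, cnt$promoter_genes,
              cnt$mixed_regions_excluded))
  cat(sprintf("  DE genes: %d discovery-significant, %d validated\n",
              cnt$de_discovery_significant, cnt$de_validated))
  cat(sprintf("  integrated genes (inverse methylation-expression): %d\n",
              cnt$integrated_genes))
  cat(sprintf("  drug-reversible genes: %d\n", cnt$reversible_genes))
  invisible(x)
}

#' @export
summary.promethex_run <- function(object, ...) {
  print(object)
  cat("\nValidated DMP direction split:\n")
  print(object$context$overall)
  cat("\nCGI context of validated DMPs:\n")
  print(object$context$cgi)
  if (!is.null(object$crosstab)) {
    cat("\nCluster-phenotype cross-tab:\n")
    print(object$crosstab)
  }
  cat("\nTop enriched gene sets:\n")
  print(utils::head(object$enrichment, 5L))
  invisible(object)
}

#' @export
plot.promethex_run <- function(x, ...) {
  if (is.null(x$clusters)) {
    warning("no clustering available (too few integrated genes)")
    return(invisible(x))
  }
  plot(x$clusters$hclust, main = "Ward clustering of patients",
       xlab = "patients (promoter delta beta profiles)", sub = "", ...)
  invisible(x)
}
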