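#' Simulation configuration for a synthetic paired tumor-normal cohort
#'
#' Builds and validates the parameter set driving the synthetic study:
#' probe/gene counts, cohort sizes (defaults mirror a two-platform design of
#' 25 + 18 discovery and 44 validation methylation patients, and 36 + 36
#' expression patients), planted-effect fractions and magnitude, Beta-noise
#' concentration, the negative logit-linear methylation-expression coupling,
#' and nuisance parameters (mask-flag rate, detection-failure rate).
#'
#' @param seed Master seed; all generator stages derive their seeds from it.
#' @param n_probes,n_genes Array and transcriptome sizes (>= 100 / >= 20).
#' @param n_patients_discovery_450k,n_patients_discovery_epic,n_patients_validation
#'   Methylation cohort sizes.
#' @param n_expression_discovery,n_expression_validation Expression cohort
#'   sizes; drawn from the methylation discovery/validation patients.
#' @param frac_hyper_probes,frac_hypo_probes Fractions of probes planted with
#'   tumor hyper-/hypomethylation (`frac_hyper + frac_hypo <= 1`).
#' @param planted_delta Planted mean beta shift in tumors, in (0, 1).
#' @param beta_concentration Precision `kappa` of the Beta(mu*kappa,
#'   (1-mu)*kappa) noise around each probe's baseline.
#' @param n_integrated_genes Genes with promoter methylation negatively
#'   coupled to expression (half down-, half upregulated epigenetically).
#' @param n_expression_only_genes Genes differentially expressed with no
#'   methylation coupling.
#' @param coupling_slope Negative slope on the logit(beta) -> log2(FPKM+1)
#'   scale for coupled genes.
#' @param fpkm_log_sd Gaussian noise sd on the log2(FPKM+1) scale.
#' @param frac_masked Probability that each of the four mask flags is set,
#'   independently, per probe.
#' @param frac_failed_detection Fraction of probe-sample pairs with failed
#'   detection (p drawn above the 0.01 threshold).
#' @param n_gene_sets,gene_set_size_range,frac_sets_enriched Gene-set
#'   collection parameters.
#' @param frac_genes_with_reversing_drug Fraction of planted epigenetically
#'   regulated genes given an opposing drug interaction.
#' @return A validated list of class `promethex_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_probes = 5000L,
                       n_genes = 500L,
                       n_patients_discovery_450k = 25L,
                       n_patients_discovery_epic = 18L,
                       n_patients_validation = 44L,
                       n_expression_discovery = 36L,
                       n_expression_validation = 36L,
                       frac_hyper_probes = 0.05,
                       frac_hypo_probes = 0.03,
                       planted_delta = 0.3,
                       beta_concentration = 50,
                       n_integrated_genes = 40L,
                       n_expression_only_genes = 20L,
                       coupling_slope = -2,
                       fpkm_log_sd = 0.3,
                       frac_masked = 0.02,
                       frac_failed_detection = 2e-4,
                       n_gene_sets = 50L,
                       gene_set_size_range = c(10L, 50L),
                       frac_sets_enriched = 0.2,
                       frac_genes_with_reversing_drug = 0.7) {
  cfg <- list(seed = as.integer(seed), n_probes = as.integer(n_probes),
              n_genes = as.integer(n_genes),
              n_patients_discovery_450k = as.integer(n_patients_discovery_450k),
              n_patients_discovery_epic = as.integer(n_patients_discovery_epic),
              n_patients_validation = as.integer(n_patients_validation),
              n_expression_discovery = as.integer(n_expression_discovery),
              n_expression_validation = as.integer(n_expression_validation),
              frac_hyper_probes = frac_hyper_probes,
              frac_hypo_probes = frac_hypo_probes,
              planted_delta = planted_delta,
              beta_concentration = beta_concentration,
              n_integrated_genes = as.integer(n_integrated_genes),
              n_expression_only_genes = as.integer(n_expression_only_genes),
              coupling_slope = coupling_slope,
              fpkm_log_sd = fpkm_log_sd,
              frac_masked = frac_masked,
              frac_failed_detection = frac_failed_detection,
              n_gene_sets = as.integer(n_gene_sets),
              gene_set_size_range = as.integer(gene_set_size_range),
              frac_sets_enriched = frac_sets_enriched,
              frac_genes_with_reversing_drug = frac_genes_with_reversing_drug)
  if (cfg$n_probes < 100L) .cfg_stop("n_probes must be >= 100")
  if (cfg$n_genes < 20L) .cfg_stop("n_genes must be >= 20")
  sizes <- c(cfg$n_patients_discovery_450k, cfg$n_patients_discovery_epic,
             cfg$n_patients_validation, cfg$n_expression_discovery,
             cfg$n_expression_validation)
  if (any(sizes < 2L)) .cfg_stop("all cohort sizes must be >= 2")
  for (nm in c("frac_hyper_probes", "frac_hypo_probes", "frac_masked",
               "frac_failed_detection", "frac_sets_enriched",
               "frac_genes_with_reversing_drug"))
    .check_prob(cfg[[nm]], nm)
  if (cfg$frac_hyper_probes + cfg$frac_hypo_probes > 1)
    .cfg_stop("frac_hyper_probes + frac_hypo_probes must be <= 1")
  if (cfg$planted_delta <= 0 || cfg$planted_delta >= 1)
    .cfg_stop("planted_delta must lie in (0, 1)")
  if (cfg$beta_concentration <= 0) .cfg_stop("beta_concentration must be positive")
  if (cfg$coupling_slope >= 0) .cfg_stop("coupling_slope must be negative")
  if (cfg$fpkm_log_sd < 0) .cfg_stop("fpkm_log_sd must be non-negative")
  n_disc <- cfg$n_patients_discovery_450k + cfg$n_patients_discovery_epic
  if (cfg$n_expression_discovery > n_disc ||
      cfg$n_expression_validation > cfg$n_patients_validation)
    .cfg_stop("expression cohorts must fit inside the methylation cohorts")
  if (cfg$n_integrated_genes + cfg$n_expression_only_genes > cfg$n_genes)
    .cfg_stop("planted gene classes exceed n_genes")
  structure(cfg, class = "promethex_sim_config")
}

#' @noRd
.promoter_regions <- c("TSS1500", "TSS200", "5UTR", "1stExon")

#' Generate a synthetic probe annotation table
#'
#' One row per CpG probe: chromosome (about 2% on sex chromosomes, genes kept
#' autosomal), 1-based position, array membership (`both` / `EPIC_only` /
#' `450K_only`), CpG-island relation (promoter probes skew to islands, distal
#' probes to open sea), design type (Infinium I/II) and CpG-count covariate,
#' gene-region assignments (a probe may serve several genes), and four
#' independent Bernoulli(`frac_masked`) mask flags.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `probe_id`, `chrom`, `pos`, `array`,
#'   `cgi_relation`, `design_type`, `cpg_count`, `gene_regions` (string
#'   `"gene:region;gene:region"`, empty for intergenic probes) and the four
#'   logical flags.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "promethex_sim_config"))
  set.seed(.stage_seed(config$seed, "annotation"))
  np <- config$n_probes; ng <- config$n_genes
  probe_id <- sprintf("cg%07d", seq_len(np))
  gene_id <- sprintf("g%04d", seq_len(ng))

  # per-gene probe layout: 1-4 promoter probes, 0-3 body, occasional 3'UTR
  n_prom <- sample(1:4, ng, replace = TRUE, prob = c(0.25, 0.35, 0.25, 0.15))
  n_body <- sample(0:3, ng, replace = TRUE, prob = c(0.3, 0.35, 0.25, 0.1))
  n_utr3 <- stats::rbinom(ng, 1L, 0.2)
  need <- sum(n_prom + n_body + n_utr3)
  if (need > 0.8 * np)
    .cfg_stop("n_probes too small for the gene layout (need >= ", ceiling(need / 0.8), ")")

  gene_chrom <- sample(as.character(1:22), ng, replace = TRUE)
  gene_tss <- sample.int(1e8L, ng, replace = TRUE) + 2e4L

  assigned <- sample.int(np, need)     # probes serving genes
  chrom <- character(np); pos <- integer(np)
  gene_regions <- character(np); gene_regions[] <- ""
  is_promoter <- logical(np)
  cur <- 1L
  for (g in seq_len(ng)) {
    k <- n_prom[g] + n_body[g] + n_utr3[g]
    idx <- assigned[cur:(cur + k - 1L)]; cur <- cur + k
    regs <- c(sample(.promoter_regions, n_prom[g], replace = TRUE),
              rep("body", n_body[g]), rep("3UTR", n_utr3[g]))
    offs <- c(-sample.int(1500L, n_prom[g], replace = TRUE),
              sample.int(10000L, n_body[g] + n_utr3[g], replace = TRUE))
    chrom[idx] <- gene_chrom[g]
    pos[idx] <- pmax(1L, gene_tss[g] + offs)
    gene_regions[idx] <- paste0(gene_id[g], ":", regs)
    is_promoter[idx] <- regs %in% .promoter_regions
  }
  inter <- which(gene_regions == "")
  sex <- stats::runif(length(inter)) < 0.025
  chrom[inter] <- ifelse(sex, sample(c("X", "Y"), length(inter), replace = TRUE),
                         sample(as.character(1:22), length(inter), replace = TRUE))
  pos[inter] <- sample.int(1e8L, length(inter), replace = TRUE)

  # a small share of gene probes also serves a second gene (multi-gene mapping)
  multi <- sample(setdiff(seq_len(np), inter),
                  size = max(1L, round(0.02 * (np - length(inter)))))
  second <- sample(gene_id, length(multi), replace = TRUE)
  second_reg <- sample(c("body", "TSS1500", "3UTR"), length(multi),
                       replace = TRUE, prob = c(0.6, 0.2, 0.2))
  gene_regions[multi] <- paste0(gene_regions[multi], ";", second, ":", second_reg)

  cgi <- character(np)
  cgi[is_promoter] <- sample(c("island", "shore", "shelf", "open_sea"),
                             sum(is_promoter), replace = TRUE,
                             prob = c(0.60, 0.25, 0.05, 0.10))
  cgi[!is_promoter] <- sample(c("island", "shore", "shelf", "open_sea"),
                              sum(!is_promoter), replace = TRUE,
                              prob = c(0.08, 0.12, 0.15, 0.65))
  data.frame(
    probe_id = probe_id, chrom = chrom, pos = pos,
    array = sample(c("both", "EPIC_only", "450K_only"), np, replace = TRUE,
                   prob = c(0.80, 0.15, 0.05)),
    cgi_relation = cgi,
    design_type = sample(c("I", "II"), np, replace = TRUE, prob = c(0.2, 0.8)),
    cpg_count = sample(1:3, np, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
    gene_regions = gene_regions,
    multi_mapped = stats::runif(np) < config$frac_masked,
    repeat_overlap = stats::runif(np) < config$frac_masked,
    snp_within_10bp = stats::runif(np) < config$frac_masked,
    indel_overlap = stats::runif(np) < config$frac_masked,
    stringsAsFactors = FALSE)
}

#' Generate the cohort design table with clinical covariates
#'
#' Patients are laid out as: discovery 450K, discovery EPIC, validation EPIC
#' (methylation), with the expression discovery/validation cohorts drawn from
#' the corresponding methylation cohorts. Clinical covariates (T stage, nodal
#' status, age, gender, risk habit) follow frequencies typical of a
#' gingivo-buccal oral cancer case series; a few stage entries are left
#' missing to exercise unknown-value handling.
#'
#' @param config A [sim_config()].
#' @return Data frame with one row per patient.
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "promethex_sim_config"))
  set.seed(.stage_seed(config$seed, "design"))
  n1 <- config$n_patients_discovery_450k
  n2 <- config$n_patients_discovery_epic
  n3 <- config$n_patients_validation
  n <- n1 + n2 + n3
  patient_id <- sprintf("P%03d", seq_len(n))
  meth_cohort <- c(rep("discovery", n1 + n2), rep("validation", n3))
  platform <- c(rep("450K", n1), rep("EPIC", n2 + n3))
  expr_cohort <- rep("none", n)
  expr_cohort[seq_len(config$n_expression_discovery)] <- "discovery"
  expr_cohort[n1 + n2 + seq_len(config$n_expression_validation)] <- "validation"
  T_stage <- sample(c("T1", "T2", "T3", "T4"), n, replace = TRUE,
                    prob = c(0.11, 0.29, 0.05, 0.55))
  N_stage <- sample(c("N0", "N+"), n, replace = TRUE, prob = c(0.46, 0.54))
  T_stage[stats::runif(n) < 0.05] <- NA
  N_stage[stats::runif(n) < 0.05] <- NA
  data.frame(
    patient_id = patient_id,
    tumor_sample_id = paste0(patient_id, "_T"),
    normal_sample_id = paste0(patient_id, "_N"),
    meth_cohort = meth_cohort, platform = platform, expr_cohort = expr_cohort,
    T_stage = T_stage, N_stage = N_stage,
    age = pmin(80L, pmax(25L, round(stats::rnorm(n, 50, 11)))),
    gender = sample(c("M", "F"), n, replace = TRUE, prob = c(0.86, 0.14)),
    risk_habit = sample(c("chewing", "chewing_smoking_alcohol",
                          "smoking_alcohol", "none"),
                        n, replace = TRUE, prob = c(0.44, 0.48, 0.06, 0.02)),
    stringsAsFactors = FALSE)
}

#' @noRd
.cgi_baseline <- c(island = 0.15, shore = 0.35, shelf = 0.55, open_sea = 0.75)

#' @noRd
.logit <- function(p) {
  p <- pmin(pmax(p, 1e-3), 1 - 1e-3)
  log(p / (1 - p))
}

#' Convert a beta value and total intensity scale to channel intensities
#'
#' `m = beta * scale`, `u = (1 - beta) * scale`, so the beta formula recovers
#' `beta * scale / (scale + alpha)` -- the offset shrinkage is exercised but
#' no dye chemistry is modelled.
#'
#' @param beta Beta value(s) in `[0, 1]`.
#' @param scale Total intensity `m + u`.
#' @return List with `m` and `u`.
#' @export
beta_to_intensity <- function(beta, scale) {
  list(m = beta * scale, u = (1 - beta) * scale)
}

#' Generate paired tumor-normal methylation data with planted effects
#'
#' Normal-sample beta values are drawn Beta(mu*kappa, (1-mu)*kappa) around a
#' baseline mu set by CpG-island relation (islands low, open sea high, with
#' per-probe jitter). Planted probes shift the tumor mean by +/-
#' `planted_delta` (clamped to (0.01, 0.99)). Effects are planted on probes
#' that survive the static masks and whose baseline leaves headroom for the
#' shift: hypermethylation lands mostly on island/shore probes and
#' hypomethylation on open-sea/shelf probes, and the promoter probes of the
#' designated epigenetically regulated genes are planted first. Intensities
#' are derived per sample via a log-normal total-intensity scale, and
#' detection p values are near zero except a configurable fraction of failed
#' probe-sample pairs. Probes absent from a sample's platform are `NA`.
#'
#' @param annotation From [generate_annotation()].
#' @param design From [generate_design()].
#' @param config A [sim_config()].
#' @param intensities Also derive `m`/`u`/detection matrices (default TRUE);
#'   set FALSE for beta-only studies (e.g. calibration replicates).
#' @return List with `beta`, `m`, `u`, `detection` (probes x samples, tumor
#'   and normal columns for every methylation patient), `baseline_mu`, and
#'   `truth` (list with `probe_effects` and `gene_regulation` data frames).
#' @export
generate_methylation <- function(annotation, design, config, intensities = TRUE) {
  stopifnot(inherits(config, "promethex_sim_config"))
  set.seed(.stage_seed(config$seed, "methylation"))
  np <- nrow(annotation)
  delta <- config$planted_delta
  kappa <- config$beta_concentration

  mu <- .cgi_baseline[annotation$cgi_relation] + stats::rnorm(np, 0, 0.04)
  mu <- pmin(pmax(mu, 0.05), 0.92)
  names(mu) <- annotation$probe_id

  flagged <- annotation$multi_mapped | annotation$repeat_overlap |
    annotation$snp_within_10bp | annotation$indel_overlap
  autosomal <- !annotation$chrom %in% c("X", "Y")
  eligible <- !flagged & autosomal & annotation$array != "450K_only"
  hyper_ok <- eligible & (mu + delta) <= 0.97
  hypo_ok <- eligible & (mu - delta) >= 0.03

  map <- assign_promoter(annotation)
  prom <- map[map$region_class == "promoter", , drop = FALSE]

  effect <- rep("null", np)
  gene_class <- stats::setNames(rep("null", config$n_genes),
                                sprintf("g%04d", seq_len(config$n_genes)))
  n_down <- ceiling(config$n_integrated_genes / 2)
  n_up <- config$n_integrated_genes - n_down

  pick_genes <- function(ok_probes, n_pick, taken) {
    cand <- unique(prom$gene_id[prom$probe_id %in% annotation$probe_id[ok_probes]])
    cand <- setdiff(cand, taken)
    if (length(cand) < n_pick)
      .cfg_stop("planted_delta leaves too few genes with eligible promoter probes")
    sample(cand, n_pick)
  }
  down_genes <- pick_genes(hyper_ok, n_down, character(0))
  up_genes <- pick_genes(hypo_ok, n_up, down_genes)
  gene_class[down_genes] <- "epigenetically_down"
  gene_class[up_genes] <- "epigenetically_up"

  plant_gene_probes <- function(genes, ok_probes) {
    pid <- unique(prom$probe_id[prom$gene_id %in% genes])
    pid[pid %in% annotation$probe_id[ok_probes]]
  }
  hyper_probes <- plant_gene_probes(down_genes, hyper_ok)
  hypo_probes <- plant_gene_probes(up_genes, hypo_ok)

  # fill the remaining planted-probe budget, skewing hyper to CGIs and hypo to
  # open sea as observed on real tumor arrays; promoter probes of the
  # designated integrated genes are off limits so their regions stay
  # direction-pure and the expression coupling is not diluted
  reserved <- unique(prom$probe_id[prom$gene_id %in% c(down_genes, up_genes)])
  fill <- function(budget, already, ok, w) {
    extra <- budget - length(already)
    if (extra <= 0) return(already)
    pool <- setdiff(annotation$probe_id[ok],
                    c(hyper_probes, hypo_probes, reserved))
    if (length(pool) < extra) .cfg_stop("not enough eligible probes for the planted fractions")
    wts <- w[annotation$cgi_relation[match(pool, annotation$probe_id)]]
    c(already, sample(pool, extra, prob = wts))
  }
  hyper_probes <- fill(round(config$frac_hyper_probes * np), hyper_probes, hyper_ok,
                       c(island = 1, shore = 0.6, shelf = 0.2, open_sea = 0.15))
  hypo_probes <- fill(round(config$frac_hypo_probes * np), hypo_probes, hypo_ok,
                      c(island = 0.01, shore = 0.2, shelf = 0.6, open_sea = 1))
  effect[match(hyper_probes, annotation$probe_id)] <- "hyper"
  effect[match(hypo_probes, annotation$probe_id)] <- "hypo"

  exp_only <- sample(names(gene_class)[gene_class == "null"],
                     config$n_expression_only_genes)
  gene_class[exp_only] <- "expression_only"

  shift <- ifelse(effect == "hyper", delta, ifelse(effect == "hypo", -delta, 0))
  mu_t <- pmin(pmax(mu + shift, 0.01), 0.99)

  samples <- c(rbind(design$tumor_sample_id, design$normal_sample_id))
  is_tumor <- c(rbind(rep(TRUE, nrow(design)), rep(FALSE, nrow(design))))
  ns <- length(samples)
  a_n <- mu * kappa; b_n <- (1 - mu) * kappa
  a_t <- mu_t * kappa; b_t <- (1 - mu_t) * kappa
  beta <- matrix(NA_real_, np, ns, dimnames = list(annotation$probe_id, samples))
  for (j in seq_len(ns)) {
    beta[, j] <- if (is_tumor[j]) stats::rbeta(np, a_t, b_t) else stats::rbeta(np, a_n, b_n)
  }
  # platform availability
  platform_by_sample <- rep(design$platform, each = 2L)
  off_450k <- annotation$array == "EPIC_only"
  off_epic <- annotation$array == "450K_only"
  beta[off_450k, platform_by_sample == "450K"] <- NA
  beta[off_epic, platform_by_sample == "EPIC"] <- NA

  m <- u <- detection <- NULL
  if (intensities) {
    scale_sample <- stats::rlnorm(ns, log(1e4), 0.2)
    noise <- matrix(stats::rlnorm(np * ns, 0, 0.1), np, ns)
    S <- sweep(noise, 2L, scale_sample, `*`)
    iu <- beta_to_intensity(beta, S)
    m <- iu$m; u <- iu$u
    detection <- matrix(stats::runif(np * ns, 0, 1e-3), np, ns,
                        dimnames = dimnames(beta))
    failed <- matrix(stats::runif(np * ns) < config$frac_failed_detection, np, ns)
    detection[failed] <- stats::runif(sum(failed), 0.02, 0.5)
    detection[is.na(beta)] <- NA
  }

  truth <- list(
    probe_effects = data.frame(probe_id = annotation$probe_id, effect = effect,
                               stringsAsFactors = FALSE),
    gene_regulation = data.frame(gene_id = names(gene_class),
                                 class = unname(gene_class),
                                 stringsAsFactors = FALSE))
  list(beta = beta, m = m, u = u, detection = detection,
       baseline_mu = mu, truth = truth)
}

#' Generate FPKM expression coupled to promoter methylation
#'
#' For each epigenetically regulated gene, `log2(FPKM + 1) = baseline +
#' coupling_slope * (logit(promoter beta) - logit(baseline beta)) + noise`,
#' per sample, using that gene's planted promoter probes; expression-only
#' genes get a fixed tumor mean shift with no methylation coupling; null
#' genes are i.i.d. around their baseline. FPKM is clipped at 0.
#'
#' @param annotation,design,config As in [generate_methylation()].
#' @param beta Beta matrix from [generate_methylation()].
#' @param truth Truth ledger from [generate_methylation()].
#' @return Genes x samples FPKM matrix over the expression-cohort samples.
#' @export
generate_expression <- function(annotation, beta, truth, design, config) {
  stopifnot(inherits(config, "promethex_sim_config"))
  set.seed(.stage_seed(config$seed, "expression"))
  des <- design[design$expr_cohort != "none", , drop = FALSE]
  samples <- c(rbind(des$tumor_sample_id, des$normal_sample_id))
  is_tumor <- c(rbind(rep(TRUE, nrow(des)), rep(FALSE, nrow(des))))
  genes <- truth$gene_regulation$gene_id
  ng <- length(genes); ns <- length(samples)

  map <- assign_promoter(annotation)
  prom <- map[map$region_class == "promoter", , drop = FALSE]
  planted <- truth$probe_effects$probe_id[truth$probe_effects$effect != "null"]

  baseline <- stats::setNames(stats::rnorm(ng, 3.5, 1.2), genes)
  x <- matrix(rep(baseline, ns), ng, ns, dimnames = list(genes, samples))
  cls <- stats::setNames(truth$gene_regulation$class, genes)

  for (g in genes[cls %in% c("epigenetically_down", "epigenetically_up")]) {
    pp <- intersect(prom$probe_id[prom$gene_id == g], planted)
    if (length(pp) == 0L)
      stop("generation error: epigenetically regulated gene ", g,
           " has no planted promoter probes")
    bg <- beta[pp, samples, drop = FALSE]
    bbar <- colMeans(bg, na.rm = TRUE)
    ref <- mean(bbar[!is_tumor], na.rm = TRUE)
    x[g, ] <- x[g, ] + config$coupling_slope * (.logit(bbar) - .logit(ref))
  }
  shift_sign <- stats::setNames(sample(c(-1, 1), ng, replace = TRUE), genes)
  for (g in genes[cls == "expression_only"]) {
    x[g, is_tumor] <- x[g, is_tumor] + 2 * shift_sign[g]
  }
  x <- x + matrix(stats::rnorm(ng * ns, 0, config$fpkm_log_sd), ng, ns)
  pmax(2^x - 1, 0)
}

#' Generate a gene-set collection with planted enrichment
#'
#' A fraction of the sets draws half its members from the planted
#' epigenetically regulated genes; the rest are random. Sets are returned as
#' a named list of member vectors (the GMT in-memory form).
#'
#' @param truth Truth ledger from [generate_methylation()].
#' @param config A [sim_config()].
#' @return Named list of character vectors; the `enriched` attribute marks
#'   the planted-enrichment sets.
#' @export
generate_gene_sets <- function(truth, config) {
  stopifnot(inherits(config, "promethex_sim_config"))
  set.seed(.stage_seed(config$seed, "gene_sets"))
  genes <- truth$gene_regulation$gene_id
  planted <- truth$gene_regulation$gene_id[
    truth$gene_regulation$class %in% c("epigenetically_down", "epigenetically_up")]
  n_sets <- config$n_gene_sets
  enriched <- stats::runif(n_sets) < config$frac_sets_enriched
  rng <- config$gene_set_size_range
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("set%03d", seq_len(n_sets))
  other <- setdiff(genes, planted)
  for (i in seq_len(n_sets)) {
    size <- sample(max(2L, min(rng[1], length(genes))):min(rng[2], length(genes)), 1L)
    if (enriched[i] && length(planted)) {
      k <- min(length(planted), ceiling(size / 2))
      sets[[i]] <- unique(c(sample(planted, k),
                            sample(other, min(size - k, length(other)))))
    } else {
      sets[[i]] <- sample(genes, size)
    }
  }
  attr(sets, "enriched") <- names(sets)[enriched]
  sets
}

#' Generate a drug-gene interaction table
#'
#' For a configurable fraction of the planted epigenetically regulated genes,
#' an interaction is emitted whose direction opposes the planted
#' dysregulation (downregulated gene -> a drug that increases its
#' expression); random same- and cross-direction interactions on other genes
#' are added as background.
#'
#' @param truth,config As above.
#' @return Data frame with columns `drug`, `gene_id`, `effect`
#'   (`increases_expression` / `decreases_expression`).
#' @export
generate_drug_table <- function(truth, config) {
  stopifnot(inherits(config, "promethex_sim_config"))
  set.seed(.stage_seed(config$seed, "drugs"))
  gr <- truth$gene_regulation
  down <- gr$gene_id[gr$class == "epigenetically_down"]
  up <- gr$gene_id[gr$class == "epigenetically_up"]
  pick <- function(g) g[stats::runif(length(g)) < config$frac_genes_with_reversing_drug]
  rev_down <- pick(down); rev_up <- pick(up)
  drugs <- sprintf("drug%03d", seq_len(30L))
  out <- data.frame(
    drug = sample(drugs, length(rev_down) + length(rev_up), replace = TRUE),
    gene_id = c(rev_down, rev_up),
    effect = c(rep("increases_expression", length(rev_down)),
               rep("decreases_expression", length(rev_up))),
    stringsAsFactors = FALSE)
  n_bg <- 3L * nrow(gr) %/% 10L
  bg <- data.frame(
    drug = sample(drugs, n_bg, replace = TRUE),
    gene_id = sample(gr$gene_id, n_bg, replace = TRUE),
    effect = sample(c("increases_expression", "decreases_expression"), n_bg,
                    replace = TRUE),
    stringsAsFactors = FALSE)
  unique(rbind(out, bg))
}

#' Simulate a complete synthetic study
#'
#' Runs all generator stages from one configuration: annotation, design,
#' paired methylation (with intensities and detection p), coupled expression,
#' gene sets, and the drug table, together with the planted-truth ledger.
#' Identical configurations (including seed) give bit-identical output.
#'
#' @param config A [sim_config()].
#' @param intensities Generate intensity matrices (default TRUE).
#' @return List of class `promethex_sim` with elements `annotation`,
#'   `design`, `beta`, `m`, `u`, `detection`, `baseline_mu`, `fpkm`,
#'   `gene_sets`, `drug_table`, `truth`, `config`.
#' @export
simulate_cohort <- function(config = sim_config(), intensities = TRUE) {
  annotation <- generate_annotation(config)
  design <- generate_design(config)
  meth <- generate_methylation(annotation, design, config, intensities = intensities)
  fpkm <- generate_expression(annotation, meth$beta, meth$truth, design, config)
  gene_sets <- generate_gene_sets(meth$truth, config)
  drug_table <- generate_drug_table(meth$truth, config)
  structure(list(annotation = annotation, design = design,
                 beta = meth$beta, m = meth$m, u = meth$u,
                 detection = meth$detection, baseline_mu = meth$baseline_mu,
                 fpkm = fpkm, gene_sets = gene_sets, drug_table = drug_table,
                 truth = meth$truth, config = config),
            class = "promethex_sim")
}
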