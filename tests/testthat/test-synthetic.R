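test_that("annotation generation respects sizes, masks, and determinism", {
  cfg <- tiny_config(seed = 1, n_probes = 1000L, frac_masked = 0.05)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann), 1000L)
  # each flag ~ Binomial(1000, 0.05); allow 3 sigma around 50
  sd3 <- 3 * sqrt(1000 * 0.05 * 0.95)
  for (fl in c("multi_mapped", "repeat_overlap", "snp_within_10bp", "indel_overlap"))
    expect_lt(abs(sum(ann[[fl]]) - 50), sd3)
  expect_true(all(ann$pos >= 1))
  expect_true(all(ann$array %in% c("both", "EPIC_only", "450K_only")))
  expect_true(all(ann$cgi_relation %in% c("island", "shore", "shelf", "open_sea")))
  # same config twice: identical
  expect_identical(ann, generate_annotation(tiny_config(seed = 1, n_probes = 1000L,
                                                        frac_masked = 0.05)))
  # zero mask rate
  ann0 <- generate_annotation(tiny_config(frac_masked = 0))
  expect_equal(sum(ann0$multi_mapped | ann0$repeat_overlap |
                     ann0$snp_within_10bp | ann0$indel_overlap), 0L)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_probes = 50), "n_probes")
  expect_error(sim_config(frac_hyper_probes = 0.7, frac_hypo_probes = 0.5), "<= 1")
  expect_error(sim_config(planted_delta = 1.2), "planted_delta")
  expect_error(sim_config(n_patients_validation = 1), ">= 2")
  expect_error(sim_config(coupling_slope = 0.5), "negative")
  # a delta too large to plant anywhere gives a configuration error
  cfg_big <- tiny_config(planted_delta = 0.95)
  ann <- generate_annotation(cfg_big)
  des <- generate_design(cfg_big)
  expect_error(generate_methylation(ann, des, cfg_big), "configuration error")
})

test_that("planted effects shift tumor means by the configured delta", {
  cfg <- tiny_config(seed = 3, n_patients_discovery_450k = 20L,
                     n_patients_discovery_epic = 20L)
  ann <- generate_annotation(cfg)
  des <- generate_design(cfg)
  meth <- generate_methylation(ann, des, cfg, intensities = FALSE)
  tum <- meth$beta[, des$tumor_sample_id]
  nor <- meth$beta[, des$normal_sample_id]
  delta <- rowMeans(tum, na.rm = TRUE) - rowMeans(nor, na.rm = TRUE)
  eff <- meth$truth$probe_effects$effect
  hyper <- eff == "hyper"; hypo <- eff == "hypo"
  expect_gt(sum(hyper), 0); expect_gt(sum(hypo), 0)
  expect_lt(abs(mean(delta[hyper]) - 0.3), 0.05)
  expect_lt(abs(mean(delta[hypo]) + 0.3), 0.05)
  expect_true(all(meth$beta > 0 & meth$beta < 1, na.rm = TRUE))
  # island baseline below open-sea baseline
  expect_lt(mean(meth$baseline_mu[ann$cgi_relation == "island"]),
            mean(meth$baseline_mu[ann$cgi_relation == "open_sea"]))
})

test_that("a null cohort plants nothing and produces no large deltas", {
  cfg <- tiny_config(seed = 4, frac_hyper_probes = 0, frac_hypo_probes = 0,
                     n_integrated_genes = 0L, n_expression_only_genes = 0L)
  ann <- generate_annotation(cfg)
  des <- generate_design(cfg)
  meth <- generate_methylation(ann, des, cfg, intensities = FALSE)
  expect_true(all(meth$truth$probe_effects$effect == "null"))
  disc <- des[des$meth_cohort == "discovery", ]
  delta <- rowMeans(meth$beta[, disc$tumor_sample_id], na.rm = TRUE) -
    rowMeans(meth$beta[, disc$normal_sample_id], na.rm = TRUE)
  expect_lt(mean(abs(delta) >= 0.2, na.rm = TRUE), 0.01)
})

test_that("intensity construction satisfies m = beta*S, u = (1-beta)*S", {
  iu <- beta_to_intensity(0.5, 1000)
  expect_equal(iu$m, 500)
  expect_equal(iu$u, 500)
  # round trip through the beta formula with alpha = 0
  expect_equal(compute_beta(iu$m, iu$u, alpha = 0), 0.5)
  cfg <- tiny_config(seed = 5)
  sim <- simulate_cohort(cfg)
  ok <- !is.na(sim$m)
  expect_equal(sim$m[ok] / (sim$m[ok] + sim$u[ok]), sim$beta[ok], tolerance = 1e-12)
  expect_true(all(sim$detection[ok & !is.na(sim$detection)] >= 0))
})

test_that("expression is negatively coupled to promoter methylation", {
  cfg <- tiny_config(seed = 6, n_expression_discovery = 10L,
                     n_expression_validation = 10L,
                     n_patients_discovery_450k = 10L,
                     n_patients_discovery_epic = 10L,
                     n_patients_validation = 16L)
  sim <- simulate_cohort(cfg, intensities = FALSE)
  gr <- sim$truth$gene_regulation
  map <- assign_promoter(sim$annotation)
  planted_probes <- sim$truth$probe_effects$probe_id[
    sim$truth$probe_effects$effect != "null"]
  des <- sim$design[sim$design$expr_cohort != "none", ]
  samples <- c(des$tumor_sample_id, des$normal_sample_id)
  rhos <- sapply(gr$gene_id[gr$class %in% c("epigenetically_down",
                                            "epigenetically_up")], function(g) {
    pp <- intersect(map$probe_id[map$gene_id == g & map$region_class == "promoter"],
                    planted_probes)
    b <- colMeans(sim$beta[pp, samples, drop = FALSE], na.rm = TRUE)
    cor(b, sim$fpkm[g, samples], method = "spearman", use = "complete.obs")
  })
  expect_true(all(rhos < -0.5))
})

test_that("zero-noise monotone coupling gives exactly rho = -1", {
  cfg <- tiny_config(seed = 7, fpkm_log_sd = 0)
  sim <- simulate_cohort(cfg, intensities = FALSE)
  gr <- sim$truth$gene_regulation
  g <- gr$gene_id[gr$class == "epigenetically_down"][1]
  map <- assign_promoter(sim$annotation)
  planted <- sim$truth$probe_effects$probe_id[sim$truth$probe_effects$effect != "null"]
  pp <- intersect(map$probe_id[map$gene_id == g & map$region_class == "promoter"],
                  planted)
  des <- sim$design[sim$design$expr_cohort != "none", ]
  samples <- c(des$tumor_sample_id, des$normal_sample_id)
  b <- colMeans(sim$beta[pp, samples, drop = FALSE], na.rm = TRUE)
  y <- sim$fpkm[g, samples]
  # FPKM clipping at 0 can flatten the very lowest values; require the
  # unclipped range to stay monotone
  keep <- y > 0
  expect_equal(unname(cor(b[keep], y[keep], method = "spearman")), -1)
})

test_that("truth ledger is consistent with the generated tables", {
  cfg <- tiny_config(seed = 8)
  sim <- simulate_cohort(cfg, intensities = FALSE)
  expect_setequal(sim$truth$probe_effects$probe_id, sim$annotation$probe_id)
  expect_setequal(sim$truth$gene_regulation$gene_id, rownames(sim$fpkm))
  # every epigenetically regulated gene has planted promoter probes
  map <- assign_promoter(sim$annotation)
  planted <- sim$truth$probe_effects$probe_id[sim$truth$probe_effects$effect != "null"]
  for (g in sim$truth$gene_regulation$gene_id[
    sim$truth$gene_regulation$class %in% c("epigenetically_down", "epigenetically_up")]) {
    pp <- map$probe_id[map$gene_id == g & map$region_class == "promoter"]
    expect_gt(length(intersect(pp, planted)), 0)
  }
  # classes are mutually exclusive by construction (one label per gene)
  expect_equal(anyDuplicated(sim$truth$gene_regulation$gene_id), 0L)
})

test_that("whole-cohort simulation is deterministic in the seed", {
  a <- simulate_cohort(tiny_config(seed = 21))
  b <- simulate_cohort(tiny_config(seed = 21))
  expect_identical(a$beta, b$beta)
  expect_identical(a$m, b$m)
  expect_identical(a$fpkm, b$fpkm)
  expect_identical(a$gene_sets, b$gene_sets)
  expect_identical(a$drug_table, b$drug_table)
  c <- simulate_cohort(tiny_config(seed = 22))
  expect_false(identical(a$beta, c$beta))
})

test_that("gene sets and drug table carry the planted structure", {
  cfg <- tiny_config(seed = 9, frac_sets_enriched = 0.5)
  sim <- simulate_cohort(cfg, intensities = FALSE)
  planted <- sim$truth$gene_regulation$gene_id[
    sim$truth$gene_regulation$class %in% c("epigenetically_down", "epigenetically_up")]
  enriched <- attr(sim$gene_sets, "enriched")
  expect_gt(length(enriched), 0)
  frac_in <- sapply(sim$gene_sets, function(s) mean(s %in% planted))
  expect_gt(mean(frac_in[enriched]), mean(frac_in[setdiff(names(frac_in), enriched)]))
  # reversing interactions oppose the planted direction
  gr <- sim$truth$gene_regulation
  dt <- sim$drug_table
  down_hits <- dt[dt$gene_id %in% gr$gene_id[gr$class == "epigenetically_down"] &
                    dt$effect == "increases_expression", ]
  expect_gt(nrow(down_hits), 0)
  # zero reversing fraction gives only background interactions
  cfg0 <- tiny_config(seed = 9, frac_genes_with_reversing_drug = 0)
  sim0 <- simulate_cohort(cfg0, intensities = FALSE)
  expect_true(nrow(sim0$drug_table) <= nrow(dt))
})
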