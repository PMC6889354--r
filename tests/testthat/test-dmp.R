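# Shared mid-size cohort with good power: 20 + 10 discovery, 20 validation.
dmp_cfg <- tiny_config(seed = 31, n_probes = 800L,
                       n_patients_discovery_450k = 20L,
                       n_patients_discovery_epic = 10L,
                       n_patients_validation = 20L,
                       n_expression_discovery = 12L,
                       n_expression_validation = 12L)
dmp_sim <- simulate_cohort(dmp_cfg, intensities = FALSE)

test_that("planted probes are called with the right direction, nulls are not", {
  calls <- call_dmps(dmp_sim$beta, dmp_sim$design, dmp_sim$annotation, "merged")
  eff <- dmp_sim$truth$probe_effects
  merged_planted <- eff$probe_id[eff$effect != "null" &
                                   eff$probe_id %in% calls$probe_id]
  hit <- calls[calls$probe_id %in% merged_planted, ]
  expect_gt(mean(hit$significant), 0.9)
  expect_equal(hit$direction[hit$significant],
               eff$effect[match(hit$probe_id[hit$significant], eff$probe_id)])
  nulls <- calls[calls$probe_id %in% eff$probe_id[eff$effect == "null"], ]
  expect_lt(mean(nulls$significant), 0.05)
})

test_that("significance requires both the q and the delta-beta gate", {
  calls <- call_dmps(dmp_sim$beta, dmp_sim$design, dmp_sim$annotation, "merged")
  # any probe with small delta is never significant no matter how small p is
  small_delta <- abs(calls$delta_beta) < 0.2
  expect_false(any(calls$significant[small_delta]))
  expect_true(all(is.na(calls$direction[small_delta])))
  # direction mirrors the sign rule
  expect_true(all(calls$direction[!is.na(calls$direction)] ==
                    ifelse(calls$delta_beta[!is.na(calls$direction)] >= 0.2,
                           "hyper", "hypo")))
})

test_that("merged and epic_only subsets partition the tested probes", {
  m <- call_dmps(dmp_sim$beta, dmp_sim$design, dmp_sim$annotation, "merged")
  e <- call_dmps(dmp_sim$beta, dmp_sim$design, dmp_sim$annotation, "epic_only")
  expect_length(intersect(m$probe_id, e$probe_id), 0)
  arr <- dmp_sim$annotation$array[match(e$probe_id, dmp_sim$annotation$probe_id)]
  expect_true(all(arr == "EPIC_only"))
  # epic_only tests only the EPIC discovery patients
  n_epic <- sum(dmp_sim$design$meth_cohort == "discovery" &
                  dmp_sim$design$platform == "EPIC")
  expect_true(all(e$n_pairs <= n_epic))
})

test_that("delta beta is antisymmetric under label swap", {
  des_swap <- dmp_sim$design
  des_swap$tumor_sample_id <- dmp_sim$design$normal_sample_id
  des_swap$normal_sample_id <- dmp_sim$design$tumor_sample_id
  a <- call_dmps(dmp_sim$beta, dmp_sim$design, dmp_sim$annotation, "merged")
  b <- call_dmps(dmp_sim$beta, des_swap, dmp_sim$annotation, "merged")
  expect_equal(a$delta_beta, -b$delta_beta)
  expect_equal(a$p_raw, b$p_raw, tolerance = 1e-12)
  swapped <- !is.na(a$direction)
  expect_equal(b$direction[swapped],
               ifelse(a$direction[swapped] == "hyper", "hypo", "hyper"))
})

test_that("validation replicates planted DMPs and respects direction", {
  disc <- rbind(
    call_dmps(dmp_sim$beta, dmp_sim$design, dmp_sim$annotation, "merged"),
    call_dmps(dmp_sim$beta, dmp_sim$design, dmp_sim$annotation, "epic_only"))
  val <- validate_dmps(disc, dmp_sim$beta, dmp_sim$design)
  eff <- dmp_sim$truth$probe_effects
  planted_sig <- val$probe_id[val$significant &
                                val$probe_id %in% eff$probe_id[eff$effect != "null"]]
  expect_gt(mean(val$validated[match(planted_sig, val$probe_id)]), 0.9)
  # validated implies discovery-significant and direction-consistent
  v <- val[val$validated, ]
  expect_true(all(v$significant))
  expect_true(all(v$validation_direction == v$direction))
  # a probe forced to the opposite discovery direction cannot validate
  forced <- val[val$validated, ][1, ]
  forced$direction <- ifelse(forced$direction == "hyper", "hypo", "hyper")
  reval <- validate_dmps(forced, dmp_sim$beta, dmp_sim$design)
  expect_false(any(reval$validated))
})

test_that("empty discovery set yields an empty validation result", {
  disc <- call_dmps(dmp_sim$beta, dmp_sim$design, dmp_sim$annotation, "merged")
  disc$significant <- FALSE
  val <- validate_dmps(disc, dmp_sim$beta, dmp_sim$design)
  expect_false(any(val$validated))
  expect_length(attr(val, "excluded_probes"), 0)
})

test_that("context summary splits directions with coherent percentages", {
  disc <- call_dmps(dmp_sim$beta, dmp_sim$design, dmp_sim$annotation, "merged")
  val <- validate_dmps(disc, dmp_sim$beta, dmp_sim$design)
  ctx <- summarize_dmp_context(val[val$validated, ], dmp_sim$annotation)
  expect_equal(sum(ctx$chromosome$n), ctx$overall$n)
  expect_equal(sum(ctx$cgi$n), ctx$overall$n)
  with(ctx$chromosome, expect_equal(pct_hyper + pct_hypo, rep(100, nrow(ctx$chromosome))))
  # hyper effects planted mostly in islands/shores: island DMPs mostly hyper
  isl <- ctx$cgi[ctx$cgi$level == "island", ]
  if (nrow(isl) && isl$n >= 5) expect_gt(isl$pct_hyper, 70)
  # degenerate all-hyper input
  fake <- data.frame(probe_id = dmp_sim$annotation$probe_id[1:10],
                     direction = "hyper")
  ctx2 <- summarize_dmp_context(fake, dmp_sim$annotation)
  expect_true(all(ctx2$chromosome$pct_hyper == 100))
})

test_that("empirical false-validation rate of null probes is controlled", {
  # 25 fully null replicates at reduced scale; probes falsely validated
  n_rep <- 25
  fp <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- tiny_config(seed = 100 + r, n_probes = 300L,
                       frac_hyper_probes = 0, frac_hypo_probes = 0,
                       n_integrated_genes = 0L, n_expression_only_genes = 0L,
                       n_patients_discovery_450k = 5L,
                       n_patients_discovery_epic = 5L,
                       n_patients_validation = 10L,
                       n_expression_discovery = 8L, n_expression_validation = 8L)
    sim <- simulate_cohort(cfg, intensities = FALSE)
    disc <- call_dmps(sim$beta, sim$design, sim$annotation, "merged")
    val <- validate_dmps(disc, sim$beta, sim$design)
    fp[r] <- mean(val$validated)
  }
  expect_lt(mean(fp), 0.05)
})
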