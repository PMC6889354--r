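test_that("beta formula reproduces its defining arithmetic", {
  expect_equal(compute_beta(0, 0), 0)
  expect_equal(compute_beta(900, 0), 0.9)
  expect_equal(compute_beta(-50, 400), 0)   # negative m clipped by the formula
  # vectorized, strictly below 1 for alpha > 0, monotone in m and u
  m <- seq(-100, 5000, by = 137)
  b <- compute_beta(m, 200)
  expect_true(all(b >= 0 & b < 1))
  expect_true(all(diff(b) >= 0))
  b2 <- compute_beta(500, seq(0, 3000, by = 100))
  expect_true(all(diff(b2) <= 0))
  expect_error(compute_beta(1, 1, alpha = -1), "non-negative")
})

test_that("detection filter excludes probes failing in any cohort sample", {
  det <- matrix(0.001, 4, 3, dimnames = list(paste0("p", 1:4), paste0("s", 1:3)))
  expect_length(detection_exclusions(det), 0)
  det["p2", "s3"] <- 0.02
  expect_equal(detection_exclusions(det), "p2")
  expect_length(detection_exclusions(det, threshold = 1), 0)
  mask <- detection_exclusions(det, scope = "per_sample")
  expect_equal(sum(mask), 1L)
  expect_true(mask["p2", "s3"])
})

test_that("static probe filters implement rules c-g", {
  ann <- data.frame(
    probe_id = paste0("p", 1:6),
    chrom = c("1", "X", "2", "chr3", "4", "Y"),
    multi_mapped = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    repeat_overlap = FALSE,
    snp_within_10bp = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    indel_overlap = FALSE)
  res <- filter_probes(ann)
  expect_setequal(res$keep, c("p1", "p5"))
  expect_equal(unname(res$removed_by_rule["g_sex_chromosome"]), 2)
  expect_equal(unname(res$removed_by_rule["e_snp_within_10bp"]), 1)
  expect_equal(unname(res$removed_by_rule["c_multi_mapped"]), 1)
  # order independence: shuffling rows never changes the kept set
  set.seed(1)
  res2 <- filter_probes(ann[sample(6), ])
  expect_setequal(res2$keep, res$keep)
  ann$chrom[1] <- "weird"
  expect_error(filter_probes(ann), "unknown chromosome")
})

test_that("SNP proximity window is inclusive and MAF-gated", {
  expect_true(snp_proximity_flag(1000, 1010, 0.05))    # distance 10, inclusive
  expect_false(snp_proximity_flag(1000, 1011, 0.05))   # distance 11
  expect_false(snp_proximity_flag(1000, 1005, 0.005))  # MAF below threshold
  expect_true(snp_proximity_flag(1000, c(2000, 995), c(0.5, 0.02)))
  expect_error(snp_proximity_flag(-5, 10, 0.5), "1-based")
})

test_that("within-array normalization is a fixed point on matched types", {
  set.seed(2)
  v <- sort(runif(40))
  beta <- matrix(c(v, v), ncol = 1,
                 dimnames = list(paste0("p", 1:80), "s1"))
  dtype <- rep(c("I", "II"), each = 40)
  out <- normalize_within_array(beta, dtype, rep(1L, 80), seed = 9)
  expect_equal(out, beta, tolerance = 1e-12)
})

test_that("within-array normalization harmonizes compressed type II values", {
  set.seed(4)
  n <- 2000
  v1 <- rbeta(n, 2, 2)
  v2 <- 0.5 + 0.55 * (rbeta(n, 2, 2) - 0.5)   # type II compressed toward 0.5
  beta <- matrix(c(v1, v2), ncol = 1)
  rownames(beta) <- paste0("p", seq_len(2 * n))
  dtype <- rep(c("I", "II"), each = n)
  out <- normalize_within_array(beta, dtype, rep(1L, 2 * n), seed = 5)
  expect_lt(abs(median(out[dtype == "I", 1]) - median(out[dtype == "II", 1])), 0.01)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("within-array normalization leaves a single design type unchanged", {
  set.seed(6)
  beta <- matrix(runif(30), ncol = 1, dimnames = list(paste0("p", 1:30), "s"))
  out <- normalize_within_array(beta, rep("II", 30), rep(2L, 30), seed = 1)
  expect_equal(out, beta)
})

test_that("between-sample quantile normalization matches the definition", {
  m <- cbind(s1 = c(0.1, 0.2, 0.3), s2 = c(0.2, 0.4, 0.6))
  rownames(m) <- paste0("p", 1:3)
  out <- normalize_quantiles_between(m)
  expect_equal(unname(out[, 1]), c(0.15, 0.3, 0.45))
  expect_equal(unname(out[, 2]), c(0.15, 0.3, 0.45))

  # identical value multisets are a fixed point
  m2 <- cbind(a = c(0.5, 0.1, 0.9), b = c(0.9, 0.5, 0.1))
  expect_equal(normalize_quantiles_between(m2), m2)

  # all samples share the sorted vector afterwards; ranks preserved
  set.seed(8)
  m3 <- matrix(runif(60), 20, 3, dimnames = list(paste0("p", 1:20), paste0("s", 1:3)))
  out3 <- normalize_quantiles_between(m3)
  expect_equal(sort(out3[, 1]), sort(out3[, 2]), ignore_attr = TRUE)
  expect_equal(sort(out3[, 2]), sort(out3[, 3]), ignore_attr = TRUE)
  for (j in 1:3) expect_equal(rank(out3[, j]), rank(m3[, j]))
})

test_that("quantile normalization agrees with limma on complete data", {
  skip_if_not_installed("limma")
  set.seed(9)
  m <- matrix(runif(200), 50, 4)
  ours <- normalize_quantiles_between(m)
  ref <- limma::normalizeQuantiles(m, ties = TRUE)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("quantile normalization handles missing entries and errors", {
  m <- cbind(a = c(0.1, NA, 0.3, 0.8), b = c(0.2, 0.4, 0.6, 0.9))
  out <- normalize_quantiles_between(m)
  expect_true(is.na(out[2, 1]))
  expect_false(anyNA(out[-2, ]))
  expect_true(all(out >= 0 & out <= 1, na.rm = TRUE))
  bad <- cbind(a = c(NA_real_, NA_real_), b = c(0.1, 0.2))
  colnames(bad) <- c("a", "b")
  expect_error(normalize_quantiles_between(bad), "all-missing")
  expect_error(normalize_quantiles_between(m[, 1, drop = FALSE]), "2 samples")
})

test_that("full preprocessing keeps beta in [0,1] and reports attrition", {
  cfg <- tiny_config()
  sim <- simulate_cohort(cfg)
  pre <- preprocess_cohort(sim$m, sim$u, sim$detection, sim$annotation,
                           platform = rep(sim$design$platform, each = 2))
  expect_true(all(pre$beta >= 0 & pre$beta <= 1, na.rm = TRUE))
  att <- pre$attrition
  expect_equal(unname(att["input"] - att["detection"] - att["unannotated"] -
                        att["static_filters"]), unname(att["kept"]))
  # filtered probes are really gone
  flagged <- sim$annotation$probe_id[sim$annotation$multi_mapped |
                                       sim$annotation$chrom %in% c("X", "Y")]
  expect_length(intersect(pre$kept_probes, flagged), 0)
})
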