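# Independent brute-force oracles used to check the analytical routines.
# These deliberately share no code with the package internals.

# Exact two-sided signed-rank p by explicit enumeration of all 2^n sign
# assignments (feasible for n <= 12).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  p_le <- mean(W_all <= W_obs + 1e-9)
  p_ge <- mean(W_all >= W_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Right-tail hypergeometric probability by enumeration of all draws of size n
# from a population of N with K marked elements (feasible for N <= 20).
oracle_hypergeom_upper <- function(k, N, K, n) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  overlaps <- apply(draws, 2L, function(d) sum(d %in% marked))
  mean(overlaps >= k)
}

# All permutations of seq_len(n), built iteratively (independent of the
# package's recursive generator).
oracle_perms <- function(n) {
  out <- matrix(1L, 1L, 1L)
  for (m in 2L:n) {
    grown <- vector("list", m)
    for (pos in seq_len(m)) {
      grown[[pos]] <- cbind(out[, seq_len(pos - 1L), drop = FALSE], m,
                            out[, pos - 1L + seq_len(m - pos), drop = FALSE])
    }
    out <- do.call(rbind, grown)
  }
  out
}

# Exact two-sided permutation p for the Spearman coefficient.
oracle_spearman_perm_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perms <- oracle_perms(length(x))
  rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# Step-up BH computed literally from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Small fully in-memory cohort configuration for fast tests.
tiny_config <- function(seed = 11, ...) {
  args <- list(seed = seed, n_probes = 500L, n_genes = 30L,
               n_patients_discovery_450k = 5L, n_patients_discovery_epic = 5L,
               n_patients_validation = 10L, n_expression_discovery = 8L,
               n_expression_validation = 8L, n_integrated_genes = 6L,
               n_expression_only_genes = 4L, n_gene_sets = 10L,
               gene_set_size_range = c(5L, 15L))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
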