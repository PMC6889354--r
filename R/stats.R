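#' Paired Wilcoxon signed-rank test
#'
#' Tests equality of paired distributions (tumor vs adjacent normal values of
#' the same patients). Zero differences are dropped; the remaining absolute
#' differences are ranked with average ranks for ties, and the statistic is
#' the sum of ranks of positive differences. With `mode = "auto"` the exact
#' two-sided p value is computed by full enumeration of the 2^n' equiprobable
#' sign assignments whenever n' <= 25 (a tie-aware dynamic program over the
#' doubled ranks); larger n' uses the normal approximation with tie-corrected
#' variance and a continuity correction.
#'
#' @param x,y Equal-length numeric vectors of paired observations.
#' @param mode `"auto"` (default), `"exact"` or `"normal_approx"`.
#' @return A list with `statistic` (W), `p_value` (two-sided), `n_used`
#'   (non-zero differences) and `method`.
#' @examples
#' wilcoxon_signed_rank(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))$p_value # 0.0625
#' @export
wilcoxon_signed_rank <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p set to 1")
    return(list(statistic = NA_real_, p_value = 1, n_used = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  use_exact <- mode == "exact" || (mode == "auto" && n <= 25L)
  if (use_exact) {
    p <- .signed_rank_exact_p(r, W)
    method <- "exact"
  } else {
    p <- .signed_rank_normal_p(r, W)
    method <- "normal_approx"
  }
  list(statistic = W, p_value = p, n_used = n, method = method)
}

# Exact two-sided p by dynamic programming over doubled (hence integer) ranks:
# the null distribution of W is the distribution of a random subset sum of the
# ranks, each included with probability 1/2.
#' @noRd
.signed_rank_exact_p <- function(r, W) {
  s <- as.integer(round(2 * r))
  total <- sum(s)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (si in s) {
    f[(si + 1L):(total + 1L)] <- f[(si + 1L):(total + 1L)] + f[1L:(total + 1L - si)]
  }
  f <- f / sum(f)
  w2 <- as.integer(round(2 * W))
  p_le <- sum(f[seq_len(w2 + 1L)])
  p_ge <- sum(f[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

# Normal approximation with tie-corrected variance and continuity correction.
#' @noRd
.signed_rank_normal_p <- function(r, W) {
  n <- length(r)
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0) return(1)
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

# Row-wise paired Wilcoxon over matrices (probes x patients). Fast path uses
# the base signed-rank distribution (psignrank) for untied rows with a common
# n'; tied or zero-containing rows fall back to the scalar routine.
#' @noRd
.row_wilcoxon <- function(tumor, normal, mode = "auto") {
  stopifnot(identical(dim(tumor), dim(normal)))
  np <- nrow(tumor)
  W <- rep(NA_real_, np); P <- rep(NA_real_, np)
  n_used <- integer(np); clean <- logical(np)
  Rk <- vector("list", np)
  D <- tumor - normal
  for (i in seq_len(np)) {
    d <- D[i, ]
    d <- d[!is.na(d)]
    d <- d[d != 0]
    n <- length(d)
    n_used[i] <- n
    if (n == 0L) { P[i] <- 1; next }
    r <- rank(abs(d))
    W[i] <- sum(r[d > 0])
    tied <- anyDuplicated(r) > 0L
    clean[i] <- !tied
    if (tied) Rk[[i]] <- r
  }
  exact <- if (mode == "exact") n_used > 0L
           else if (mode == "normal_approx") rep(FALSE, np)
           else n_used > 0L & n_used <= 25L
  # untied exact rows, grouped by n' so psignrank vectorizes over W
  idx_fast <- which(exact & clean)
  for (n in unique(n_used[idx_fast])) {
    ii <- idx_fast[n_used[idx_fast] == n]
    w <- W[ii]
    p <- 2 * pmin(stats::psignrank(w, n), stats::psignrank(w - 1, n, lower.tail = FALSE))
    P[ii] <- pmin(1, p)
  }
  for (i in which(exact & !clean)) P[i] <- .signed_rank_exact_p(Rk[[i]], W[i])
  for (i in which(!exact & n_used > 0L)) {
    r <- if (clean[i]) rank(abs(D[i, ][!is.na(D[i, ]) & D[i, ] != 0])) else Rk[[i]]
    P[i] <- .signed_rank_normal_p(r, W[i])
  }
  list(statistic = W, p_value = P, n_used = n_used)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (wraps [stats::p.adjust()] with
#' input validation): `q_(i) = min_{j >= i} m * p_(j) / j`, clipped at 1.
#'
#' @param p Numeric vector of p values in `[0, 1]` (`NA` passed through).
#' @return Vector of adjusted p values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Spearman rank correlation test
#'
#' Rank correlation with average ranks for ties. The p value uses the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of
#' freedom, or, when `exact = TRUE` and `n <= exact_max`, the exact two-sided
#' permutation p by full enumeration of all n! orderings.
#'
#' @param x,y Equal-length numeric vectors, `n >= 4`.
#' @param exact Use the exact permutation null (only honoured for small n).
#' @param exact_max Largest n for which enumeration is attempted (default 8).
#' @return List with `rho`, `p_value`, `n` and `method`.
#' @export
spearman_test <- function(x, y, exact = FALSE, exact_max = 8L) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, method = "constant_input"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact && n <= exact_max) {
    perms <- .permutations(n)
    rho_perm <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t_approx"
  }
  list(rho = rho, p_value = min(1, p), n = n, method = method)
}

# All permutations of 1..n as an (n! x n) matrix, lexicographic.
#' @noRd
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row + seq_len(nrow(sub)), 1L] <- k
    out[row + seq_len(nrow(sub)), -1L] <- matrix(rest[sub], nrow(sub))
    row <- row + nrow(sub)
  }
  out
}

#' Paired t test on matched samples
#'
#' Classic paired t on the within-patient differences (wraps
#' [stats::t.test()]). A zero-variance difference vector is degenerate for the
#' t statistic; such input is flagged and the p value returned as `NA` so the
#' caller can exclude the unit.
#'
#' @param x,y Equal-length numeric vectors of paired observations, `n >= 3`.
#' @return List with `statistic`, `p_value`, `mean_difference`, `n` and
#'   `degenerate` flag.
#' @export
paired_t_test <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                mean_difference = mean(d), n = n, degenerate = TRUE))
  }
  fit <- stats::t.test(x, y, paired = TRUE)
  list(statistic = unname(fit$statistic), p_value = fit$p.value,
       mean_difference = mean(d), n = n, degenerate = FALSE)
}

#' Right-sided hypergeometric tail probability
#'
#' `P(X >= k)` for X ~ Hypergeometric(N population, K marked, n drawn), the
#' enrichment p value for observing `k` query genes inside a gene set.
#'
#' @param k Observed overlap.
#' @param N Background (population) size.
#' @param K Gene-set size within the background.
#' @param n Query size.
#' @return Upper-tail probability.
#' @export
hypergeom_upper_tail <- function(k, N, K, n) {
  stopifnot(k >= 0, K <= N, n <= N, k <= min(K, n))
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}
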