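#' Beta value from methylated/unmethylated intensities
#'
#' `beta = max(m, 0) / (max(u, 0) + max(m, 0) + alpha)`. The offset `alpha`
#' (default 100, the array manufacturer's recommendation) shrinks low-intensity
#' probes toward 0 and keeps the value strictly below 1 whenever `alpha > 0`.
#' Negative background-corrected intensities are clipped by the formula itself.
#'
#' @param m Methylated signal (vector or matrix; may be negative).
#' @param u Unmethylated signal, same shape as `m`.
#' @param alpha Non-negative offset (default 100).
#' @return Beta values in `[0, 1]`, same shape as the input; `NA` propagated.
#' @examples
#' compute_beta(900, 0)    # 0.9
#' compute_beta(-50, 400)  # 0
#' @export
compute_beta <- function(m, u, alpha = 100) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("alpha must be a single non-negative number")
  mm <- pmax(m, 0)
  uu <- pmax(u, 0)
  mm / (uu + mm + alpha)
}

#' Detection-p probe exclusion
#'
#' Rule (a) of the probe filters: a probe is dropped when its detection p
#' exceeds `threshold`. With `scope = "any"` (default) failure in any sample
#' of the analysis cohort removes the probe entirely, matching a probe-level
#' reading of the rule; `scope = "per_sample"` instead returns a logical mask
#' of failed probe-sample pairs for per-entry masking.
#'
#' @param detection Probes x samples matrix of detection p values (rownames =
#'   probe ids). `NA` entries (probe absent from a sample's array) are ignored.
#' @param threshold Failure threshold (default 0.01).
#' @param scope `"any"` or `"per_sample"`.
#' @return For `"any"`: character vector of excluded probe ids. For
#'   `"per_sample"`: logical matrix of failures.
#' @export
detection_exclusions <- function(detection, threshold = 0.01,
                                 scope = c("any", "per_sample")) {
  scope <- match.arg(scope)
  if (is.null(rownames(detection))) stop("detection matrix needs probe rownames")
  fail <- !is.na(detection) & detection > threshold
  if (scope == "per_sample") return(fail)
  rownames(detection)[rowSums(fail) > 0L]
}

#' @noRd
.norm_chrom <- function(chrom) {
  ch <- sub("^chr", "", as.character(chrom))
  ok <- ch %in% c(as.character(1:22), "X", "Y")
  if (!all(ok)) stop("validation error: unknown chromosome label(s): ",
                     paste(unique(ch[!ok]), collapse = ", "))
  ch
}

#' Static probe-exclusion rules
#'
#' Applies the annotation-based exclusion rules: (c) multi-mapped probes,
#' (d) repeat overlap, (e) polymorphic SNP within 10 bp of the interrogated
#' CpG, (f) indel overlap, and (g) sex-chromosome location. Rules are
#' order-independent: the kept set is the complement of the union, and each
#' rule's removal count includes every probe it flags (a probe can be counted
#' under several rules).
#'
#' @param annotation Data frame with columns `probe_id`, `chrom`, and logical
#'   flags `multi_mapped`, `repeat_overlap`, `snp_within_10bp`, `indel_overlap`.
#' @return List with `keep` (character probe ids) and `removed_by_rule`
#'   (named integer vector over rules c-g).
#' @export
filter_probes <- function(annotation) {
  need <- c("probe_id", "chrom", "multi_mapped", "repeat_overlap",
            "snp_within_10bp", "indel_overlap")
  miss <- setdiff(need, names(annotation))
  if (length(miss)) stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  ch <- .norm_chrom(annotation$chrom)
  rules <- cbind(
    c_multi_mapped    = as.logical(annotation$multi_mapped),
    d_repeat_overlap  = as.logical(annotation$repeat_overlap),
    e_snp_within_10bp = as.logical(annotation$snp_within_10bp),
    f_indel_overlap   = as.logical(annotation$indel_overlap),
    g_sex_chromosome  = ch %in% c("X", "Y")
  )
  rules[is.na(rules)] <- TRUE  # missing flag treated as masked (rule b spirit)
  drop <- rowSums(rules) > 0L
  list(keep = annotation$probe_id[!drop],
       removed_by_rule = colSums(rules))
}

#' SNP-proximity flag for a probe
#'
#' TRUE iff some SNP with minor allele frequency above `maf_min` lies within
#' `window` bases of the interrogated CpG position (inclusive distance,
#' `|snp - probe| <= window`). Positions are 1-based on one chromosome.
#'
#' @param probe_position 1-based CpG position.
#' @param snp_positions,snp_mafs Parallel vectors of SNP positions and MAFs.
#' @param window Proximity window in bp (default 10).
#' @param maf_min MAF must strictly exceed this (default 0.01).
#' @return Logical scalar.
#' @export
snp_proximity_flag <- function(probe_position, snp_positions, snp_mafs,
                               window = 10, maf_min = 0.01) {
  if (length(snp_positions) != length(snp_mafs))
    stop("snp_positions and snp_mafs must be parallel")
  if (probe_position < 1 || any(snp_positions < 1))
    stop("validation error: positions must be positive (1-based)")
  any(snp_mafs > maf_min & abs(snp_positions - probe_position) <= window)
}

#' Within-array type I/II subset-quantile normalization
#'
#' Harmonizes the two Infinium probe-design chemistries sample by sample, in
#' the spirit of subset-quantile (SWAN-style) normalization but operating
#' directly on beta values: probes are stratified by their CpG count (1, 2,
#' 3+); within each stratum an equal-size random subset is drawn from each
#' design type, the mean of the two subsets' sorted values defines a reference
#' distribution, and each design type's values in the stratum are mapped onto
#' it by linearly interpolated quantile mapping. Strata with fewer than two
#' usable probes of either type are skipped with a warning; a single design
#' type is returned unchanged. Deterministic for a given `seed`.
#'
#' @param beta Probes x samples matrix (rownames = probe ids); `NA` allowed.
#' @param design_type Per-probe design type, values `"I"`/`"II"`.
#' @param cpg_count Per-probe CpG-count covariate (integer; capped at 3).
#' @param seed Integer seed for the subset draws.
#' @return Normalized matrix of the same shape, values in `[0, 1]`.
#' @export
normalize_within_array <- function(beta, design_type, cpg_count, seed = 1L) {
  stopifnot(length(design_type) == nrow(beta), length(cpg_count) == nrow(beta))
  if (!all(design_type %in% c("I", "II"))) stop("design_type must be 'I' or 'II'")
  strat <- pmin(as.integer(cpg_count), 3L)
  if (anyNA(strat) || any(strat < 1L)) stop("cpg_count must be positive integers")
  out <- beta
  set.seed(as.integer(seed))
  for (j in seq_len(ncol(beta))) {
    for (s in sort(unique(strat))) {
      in_s <- strat == s & !is.na(beta[, j])
      i1 <- which(in_s & design_type == "I")
      i2 <- which(in_s & design_type == "II")
      if (length(i1) == 0L || length(i2) == 0L) next  # single type: identity
      if (length(i1) < 2L || length(i2) < 2L) {
        warning("stratum ", s, " sample ", j, " has < 2 probes of one design type; skipped")
        next
      }
      n_sub <- min(length(i1), length(i2))
      ref <- (sort(sample(beta[i1, j], n_sub)) + sort(sample(beta[i2, j], n_sub))) / 2
      out[i1, j] <- .quantile_map(beta[i1, j], ref)
      out[i2, j] <- .quantile_map(beta[i2, j], ref)
    }
  }
  out
}

# Map values onto a sorted reference distribution by rank position with
# linear interpolation; when the value set equals the reference this is the
# identity.
#' @noRd
.quantile_map <- function(v, ref) {
  m <- length(v)
  k <- length(ref)
  rk <- rank(v, ties.method = "average")
  pos <- if (m == 1L) 0.5 else (rk - 1) / (m - 1)
  stats::approx(seq(0, 1, length.out = k), ref, xout = pos)$y
}

#' Between-sample quantile normalization of beta values
#'
#' Classical full quantile normalization across samples: each sample's sorted
#' values are replaced by the across-sample mean of order statistics; tied
#' values (average ranks) receive the mean of the reference values they span
#' via linear interpolation. Missing entries are left missing and excluded
#' from rank computation; samples with fewer non-missing values than the
#' reference grid are mapped through interpolated quantiles.
#'
#' @param mat Probes x samples matrix, at least two samples.
#' @return Matrix of the same shape; after normalization all complete samples
#'   share one sorted value vector.
#' @export
normalize_quantiles_between <- function(mat) {
  if (ncol(mat) < 2L) stop("need at least 2 samples")
  n_ok <- colSums(!is.na(mat))
  if (any(n_ok == 0L)) stop("sample(s) with all-missing values: ",
                            paste(colnames(mat)[n_ok == 0L], collapse = ", "))
  n <- nrow(mat)
  grid <- if (n == 1L) 0.5 else (seq_len(n) - 1) / (n - 1)
  qs <- vapply(seq_len(ncol(mat)), function(j) {
    v <- sort(mat[, j], na.last = NA)
    if (length(v) == n) v
    else stats::approx(seq(0, 1, length.out = length(v)), v, xout = grid)$y
  }, numeric(n))
  ref <- rowMeans(qs)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    ok <- !is.na(mat[, j])
    m <- sum(ok)
    rk <- rank(mat[ok, j], ties.method = "average")
    pos <- if (m == 1L) 0.5 else (rk - 1) / (m - 1)
    out[ok, j] <- stats::approx(grid, ref, xout = pos)$y
  }
  out
}

#' Preprocess a cohort from raw intensities to a clean beta matrix
#'
#' Runs the full preprocessing chain: beta computation with offset `alpha`,
#' detection-p exclusion, static probe filters (rules c-g), within-array
#' type I/II harmonization, and between-sample quantile normalization run
#' separately per array platform (so each platform is normalized over the
#' probes it actually measures) before the matrices are merged.
#'
#' @param m,u,detection Probes x samples matrices (shared dimnames); entries
#'   `NA` where a probe is absent from a sample's platform.
#' @param annotation Probe annotation data frame (see [filter_probes()]);
#'   must also carry `design_type` and `cpg_count` when `normalize = TRUE`.
#' @param platform Per-sample platform labels (e.g. `"450K"`/`"EPIC"`).
#' @param alpha Beta offset (default 100).
#' @param detection_threshold Detection-p failure threshold (default 0.01).
#' @param normalize Apply the two normalization steps (default TRUE).
#' @param seed Seed for the within-array subset draws.
#' @return List with `beta` (clean normalized matrix), `kept_probes`, and
#'   `attrition` (named counts removed at each step).
#' @export
preprocess_cohort <- function(m, u, detection, annotation, platform,
                              alpha = 100, detection_threshold = 0.01,
                              normalize = TRUE, seed = 1L) {
  stopifnot(identical(dim(m), dim(u)), identical(dim(m), dim(detection)))
  if (length(platform) != ncol(m)) stop("platform must have one entry per sample")
  beta <- compute_beta(m, u, alpha)
  dimnames(beta) <- dimnames(m)
  n0 <- nrow(beta)

  det_drop <- detection_exclusions(detection, detection_threshold, scope = "any")
  beta <- beta[!rownames(beta) %in% det_drop, , drop = FALSE]

  ann <- annotation[match(rownames(beta), annotation$probe_id), , drop = FALSE]
  unannotated <- rownames(beta)[is.na(ann$probe_id)]  # rule (b): NA-masked
  beta <- beta[!rownames(beta) %in% unannotated, , drop = FALSE]
  ann <- annotation[match(rownames(beta), annotation$probe_id), , drop = FALSE]

  flt <- filter_probes(ann)
  n_before_static <- nrow(beta)
  beta <- beta[rownames(beta) %in% flt$keep, , drop = FALSE]
  ann <- ann[match(rownames(beta), ann$probe_id), , drop = FALSE]

  if (normalize && nrow(beta) > 1L) {
    beta <- normalize_within_array(beta, ann$design_type, ann$cpg_count, seed = seed)
    for (pf in unique(platform)) {
      cols <- which(platform == pf)
      if (length(cols) >= 2L) {
        present <- rowSums(!is.na(beta[, cols, drop = FALSE])) > 0L
        beta[present, cols] <- normalize_quantiles_between(
          beta[present, cols, drop = FALSE])
      }
    }
  }
  list(beta = beta,
       kept_probes = rownames(beta),
       attrition = c(input = n0,
                     detection = length(det_drop),
                     unannotated = length(unannotated),
                     static_filters = n_before_static - nrow(beta),
                     kept = nrow(beta)))
}
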