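#' Call differentially methylated probes in the discovery cohort
#'
#' Per probe, a paired Wilcoxon signed-rank test compares tumor and normal
#' beta values across the discovery patients, with Benjamini-Hochberg
#' correction over all probes tested in the subset. The `"merged"` subset
#' tests probes present on both array platforms over all discovery patients;
#' `"epic_only"` tests EPIC-exclusive probes over the EPIC-platform discovery
#' patients only, at a stricter threshold. A probe is significant iff its
#' adjusted p is below the subset threshold AND `|delta_beta| >= min_delta`;
#' direction is hyper for `delta_beta >= min_delta`, hypo for
#' `delta_beta <= -min_delta`.
#'
#' @param beta Probes x samples beta matrix (preprocessed).
#' @param design Cohort design data frame (one row per patient with
#'   `tumor_sample_id`, `normal_sample_id`, `meth_cohort`, `platform`).
#' @param annotation Probe annotation with `probe_id` and `array`.
#' @param subset `"merged"` or `"epic_only"`.
#' @param q_threshold Adjusted-p cutoff; defaults to 0.05 for merged and
#'   0.02 for epic_only.
#' @param min_delta Minimum absolute mean beta difference (default 0.2).
#' @param mode Wilcoxon p-value mode passed through (default `"auto"`).
#' @return Data frame (one row per tested probe): `probe_id`, `subset`,
#'   `n_pairs`, `statistic`, `p_raw`, `p_adj`, `delta_beta`, `direction`
#'   (`NA` when `|delta_beta| < min_delta`), `significant`.
#' @export
call_dmps <- function(beta, design, annotation,
                      subset = c("merged", "epic_only"),
                      q_threshold = NULL, min_delta = 0.2, mode = "auto") {
  subset <- match.arg(subset)
  q <- q_threshold %||% if (subset == "merged") 0.05 else 0.02
  des <- design[design$meth_cohort == "discovery", , drop = FALSE]
  if (subset == "epic_only") des <- des[des$platform == "EPIC", , drop = FALSE]
  if (nrow(des) < 2L) stop("fewer than 2 discovery patients for subset ", subset)
  want <- annotation$probe_id[
    if (subset == "merged") annotation$array == "both"
    else annotation$array == "EPIC_only"]
  probes <- intersect(rownames(beta), want)
  if (length(probes) == 0L) stop("no probes to test in subset ", subset)
  tum <- beta[probes, des$tumor_sample_id, drop = FALSE]
  nor <- beta[probes, des$normal_sample_id, drop = FALSE]
  res <- .row_wilcoxon(tum, nor, mode = mode)
  delta <- rowMeans(tum, na.rm = TRUE) - rowMeans(nor, na.rm = TRUE)
  p_adj <- bh_adjust(res$p_value)
  direction <- ifelse(delta >= min_delta, "hyper",
                      ifelse(delta <= -min_delta, "hypo", NA_character_))
  data.frame(probe_id = probes, subset = subset, n_pairs = res$n_used,
             statistic = res$statistic, p_raw = res$p_value, p_adj = p_adj,
             delta_beta = unname(delta), direction = direction,
             significant = p_adj < q & !is.na(direction),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Validate discovery DMPs in the independent validation cohort
#'
#' Only discovery-significant probes are re-tested in the validation cohort;
#' by default the Benjamini-Hochberg correction is applied over exactly that
#' set (the two-stage design), with correction over all discovery-tested
#' probes available via `universe = "all_tested"`. A probe is validated iff
#' its validation adjusted p is below `q_threshold`, its validation
#' `|delta_beta| >= min_delta`, and (by default) its direction agrees with
#' discovery. Discovery-significant probes absent from the validation matrix
#' are excluded and reported in the `excluded_probes` attribute.
#'
#' @param discovery_calls Output of [call_dmps()] (possibly several subsets
#'   row-bound).
#' @param beta,design As in [call_dmps()]; validation patients are the rows
#'   with `meth_cohort == "validation"`.
#' @param q_threshold Validation adjusted-p cutoff (default 0.05).
#' @param min_delta Minimum absolute validation delta beta (default 0.2).
#' @param require_direction_consistency Default TRUE.
#' @param universe BH universe: `"discovery_significant"` (default) or
#'   `"all_tested"`.
#' @param mode Wilcoxon mode (default `"auto"`).
#' @return The discovery table augmented with `validation_p_raw`,
#'   `validation_p_adj`, `validation_delta_beta`, `validation_direction`,
#'   `validated` (FALSE for probes not significant in discovery or absent
#'   from validation).
#' @export
validate_dmps <- function(discovery_calls, beta, design,
                          q_threshold = 0.05, min_delta = 0.2,
                          require_direction_consistency = TRUE,
                          universe = c("discovery_significant", "all_tested"),
                          mode = "auto") {
  universe <- match.arg(universe)
  des <- design[design$meth_cohort == "validation", , drop = FALSE]
  if (nrow(des) < 2L) stop("fewer than 2 validation patients")
  out <- discovery_calls
  out$validation_p_raw <- NA_real_
  out$validation_p_adj <- NA_real_
  out$validation_delta_beta <- NA_real_
  out$validation_direction <- NA_character_
  out$validated <- FALSE
  if (!any(discovery_calls$significant)) {
    attr(out, "excluded_probes") <- character(0)
    return(out)
  }
  test_set <- if (universe == "discovery_significant")
    discovery_calls$probe_id[discovery_calls$significant]
  else discovery_calls$probe_id
  present <- test_set[test_set %in% rownames(beta)]
  present <- present[rowSums(!is.na(beta[present, c(des$tumor_sample_id,
                                                    des$normal_sample_id),
                                         drop = FALSE])) > 0L]
  excluded <- setdiff(discovery_calls$probe_id[discovery_calls$significant], present)
  if (length(present)) {
    tum <- beta[present, des$tumor_sample_id, drop = FALSE]
    nor <- beta[present, des$normal_sample_id, drop = FALSE]
    res <- .row_wilcoxon(tum, nor, mode = mode)
    delta <- rowMeans(tum, na.rm = TRUE) - rowMeans(nor, na.rm = TRUE)
    p_adj <- bh_adjust(res$p_value)
    i <- match(present, out$probe_id)
    out$validation_p_raw[i] <- res$p_value
    out$validation_p_adj[i] <- p_adj
    out$validation_delta_beta[i] <- unname(delta)
    out$validation_direction[i] <- ifelse(delta >= min_delta, "hyper",
                                          ifelse(delta <= -min_delta, "hypo",
                                                 NA_character_))
    ok <- out$significant &
      !is.na(out$validation_p_adj) & out$validation_p_adj < q_threshold &
      !is.na(out$validation_direction)
    if (require_direction_consistency)
      ok <- ok & !is.na(out$direction) &
        out$validation_direction == out$direction
    out$validated <- ok & !is.na(ok)
  }
  attr(out, "excluded_probes") <- excluded
  out
}

#' Genomic-context summary of DMP calls
#'
#' Per-chromosome and per-CGI-relation breakdowns of (validated) DMPs, split
#' by direction, with percentages computed by [percent()]. Within each
#' breakdown the direction percentages sum to 100.
#'
#' @param calls A DMP table with `probe_id` and `direction`; typically the
#'   validated rows of [validate_dmps()] output.
#' @param annotation Probe annotation (`probe_id`, `chrom`, `cgi_relation`).
#' @return List with data frames `chromosome` and `cgi`, plus `overall`
#'   (total, hyper/hypo counts and percentages).
#' @export
summarize_dmp_context <- function(calls, annotation) {
  calls <- calls[!is.na(calls$direction), , drop = FALSE]
  ann <- annotation[match(calls$probe_id, annotation$probe_id), , drop = FALSE]
  total <- nrow(calls)
  tab <- function(key) {
    if (total == 0L)
      return(data.frame(level = character(0), n = integer(0),
                        n_hyper = integer(0), n_hypo = integer(0),
                        pct_hyper = numeric(0), pct_hypo = numeric(0),
                        pct_of_all = numeric(0)))
    lv <- sort(unique(key))
    n <- vapply(lv, function(l) sum(key == l), 0L)
    nh <- vapply(lv, function(l) sum(key == l & calls$direction == "hyper"), 0L)
    data.frame(level = lv, n = n, n_hyper = nh, n_hypo = n - nh,
               pct_hyper = percent(nh, n, 1), pct_hypo = percent(n - nh, n, 1),
               pct_of_all = percent(n, total, 1),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  n_hyper <- sum(calls$direction == "hyper")
  list(chromosome = tab(ann$chrom),
       cgi = tab(ann$cgi_relation),
       overall = data.frame(
         n = total, n_hyper = n_hyper, n_hypo = total - n_hyper,
         pct_hyper = if (total) percent(n_hyper, total, 1) else NA_real_,
         pct_hypo = if (total) percent(total - n_hyper, total, 1) else NA_real_))
}
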