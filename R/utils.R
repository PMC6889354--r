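#' Percentage of a count within a total
#'
#' Small summary helper used throughout the context-summary tables:
#' `100 * n / total`, rounded to `digits` decimal places.
#'
#' @param n Numerator count (vectorized).
#' @param total Denominator count.
#' @param digits Decimal places to round to (default 0, i.e. whole percent).
#' @return Numeric vector of percentages.
#' @examples
#' percent(1734, 2207, 1) # 78.6
#' @export
percent <- function(n, total, digits = 0) {
  if (any(total == 0)) stop("percent(): zero denominator")
  round(100 * n / total, digits)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop with a consistent "configuration error" prefix.
#' @noRd
.cfg_stop <- function(...) stop("configuration error: ", ..., call. = FALSE)

# Validate a probability-like scalar.
#' @noRd
.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    .cfg_stop(name, " must be a single value in [0, 1]")
  invisible(x)
}

# Deterministic stage-seed fan-out from one master seed. Offsets keep all
# derived seeds well below .Machine$integer.max.
#' @noRd
.stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  if (seed < 0 || seed > 2^31 - 1000) .cfg_stop("seed must lie in [0, 2^31 - 1000]")
  offsets <- c(annotation = 1L, design = 2L, methylation = 3L, expression = 4L,
               gene_sets = 5L, drugs = 6L, preprocess = 7L, pipeline = 8L)
  off <- offsets[[stage]]
  if (is.null(off)) stop("unknown stage: ", stage)
  as.integer(seed) + off
}
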