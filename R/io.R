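#' Write a labelled numeric matrix as TSV
#'
#' Header row, row-label first column, "." decimal, `NA` for missing; UTF-8.
#'
#' @param mat Matrix with row and column names.
#' @param path Output path.
#' @param label Name for the row-label column (default `"id"`).
#' @export
write_matrix_tsv <- function(mat, path, label = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a labelled numeric matrix from TSV
#'
#' Inverse of [write_matrix_tsv()]: first column gives row labels, remaining
#' columns are parsed numerically with "NA" as missing. Ragged rows and
#' duplicate labels raise a parse error naming the line/label.
#'
#' @param path Input path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stop("parse error: empty file ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(cells[[1L]])
  bad <- which(lengths(cells) != width)
  if (length(bad))
    stop("parse error: ragged row at line ", bad[1L], " of ", path)
  header <- cells[[1L]][-1L]
  ids <- vapply(cells[-1L], `[[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("parse error: duplicate row label '", dup[1L], "' in ", path)
  body <- vapply(cells[-1L], function(r) {
    v <- r[-1L]
    v[v == "NA" | v == ""] <- NA_character_
    as.numeric(v)
  }, numeric(width - 1L))
  mat <- if (is.matrix(body)) t(body) else matrix(body, ncol = width - 1L)
  dimnames(mat) <- list(ids, header)
  mat
}

#' Read a GMT gene-set file
#'
#' One set per tab-separated line: name, description, members. Lines with
#' fewer than three fields are a parse error.
#'
#' @param path Input path.
#' @return Named list of member vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- list()
    attr(out, "descriptions") <- character(0)
    return(out)
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(cells) < 3L)
  if (length(short))
    stop("parse error: GMT line ", short[1L], " has fewer than 3 fields")
  out <- lapply(cells, function(r) r[-(1:2)])
  names(out) <- vapply(cells, `[[`, "", 1L)
  attr(out, "descriptions") <- stats::setNames(
    vapply(cells, `[[`, "", 2L), names(out))
  out
}

#' Write gene sets in GMT dialect
#'
#' @param sets Named list of member vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (default `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% attr(sets, "descriptions") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(s)
    paste(c(s, desc[[s]] %||% "na", sets[[s]]), collapse = "\t"), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a BED interval file
#'
#' BED is 0-based half-open; the returned table carries the raw `start`/
#' `end` plus the 1-based inclusive coordinates `start1 = start + 1`,
#' `end1 = end` used internally (a single-base feature `9 10` is the
#' 1-based point 10).
#'
#' @param path Input path.
#' @return Data frame: `chrom`, `start`, `end`, `start1`, `end1`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), start1 = integer(0),
                      end1 = integer(0), stringsAsFactors = FALSE))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(cells) < 3L)
  if (length(short))
    stop("parse error: BED line ", short[1L], " has fewer than 3 fields")
  start <- as.integer(vapply(cells, `[[`, "", 2L))
  end <- as.integer(vapply(cells, `[[`, "", 3L))
  data.frame(chrom = vapply(cells, `[[`, "", 1L),
             start = start, end = end,
             start1 = start + 1L, end1 = end,
             stringsAsFactors = FALSE)
}

#' Write a data frame as TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Input path.
#' @return Data frame (strings not coerced to factors).
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = "NA")
}

#' Write all synthetic-cohort inputs to a directory
#'
#' Emits the annotation, design, per-sample intensity tables (probe_id, m,
#' u, detection_p), FPKM matrix, gene sets (GMT), drug table, and truth
#' ledger, all as plain TSV/GMT.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "promethex_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(sim$annotation, file.path(dir, "annotation.tsv"))
  write_tsv(sim$design, file.path(dir, "design.tsv"))
  write_matrix_tsv(sim$fpkm, file.path(dir, "fpkm.tsv"), label = "gene_id")
  write_gmt(sim$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_tsv(sim$drug_table, file.path(dir, "drugs.tsv"))
  write_tsv(sim$truth$probe_effects, file.path(dir, "truth_probes.tsv"))
  write_tsv(sim$truth$gene_regulation, file.path(dir, "truth_genes.tsv"))
  if (!is.null(sim$m)) {
    idir <- file.path(dir, "intensities")
    dir.create(idir, showWarnings = FALSE)
    for (s in colnames(sim$m)) {
      keep <- !is.na(sim$m[, s])
      write_tsv(data.frame(probe_id = rownames(sim$m)[keep],
                           m = sim$m[keep, s], u = sim$u[keep, s],
                           detection_p = sim$detection[keep, s]),
                file.path(idir, paste0(s, ".tsv")))
    }
  }
  invisible(dir)
}
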