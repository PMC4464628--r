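#' Read a 12-column tabular homology hit table
#'
#' Standard tabular alignment output (query, subject, identity, alignment
#' length, mismatches, gap opens, qstart, qend, sstart, send, evalue,
#' bitscore), tab-separated, no header.
#'
#' @param path TSV path.
#' @return data.frame with columns `query_id`, `subject_id`, `identity_pct`,
#'   `align_len`, `evalue`, `bitscore` (one row per hit; empty file gives an
#'   empty table).
#' @export
read_hits_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      identity_pct = numeric(0), align_len = integer(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 12L)
  if (length(bad)) {
    stop("malformed hit row (fewer than 12 columns) at line ", bad[1L],
         " of ", path)
  }
  col <- function(k) vapply(fields, `[`, character(1), k)
  num <- function(k, what) {
    v <- suppressWarnings(as.numeric(col(k)))
    if (anyNA(v)) stop("non-numeric ", what, " at line ", which(is.na(v))[1L],
                       " of ", path)
    v
  }
  out <- data.frame(query_id = col(1L), subject_id = col(2L),
                    identity_pct = num(3L, "identity"),
                    align_len = as.integer(num(4L, "alignment length")),
                    evalue = num(11L, "e-value"),
                    bitscore = num(12L, "bitscore"),
                    stringsAsFactors = FALSE)
  if (any(out$evalue < 0) || any(out$align_len < 1L)) {
    stop("hit table violates evalue >= 0 / align_len >= 1 in ", path)
  }
  out
}

#' Construct a count matrix with replicate structure
#'
#' @param counts numeric matrix, transcripts in rows (rownames = transcript
#'   ids), samples in columns (colnames = sample labels); entries are
#'   non-negative fragment counts (possibly non-integer, as produced by
#'   expectation-based quantifiers).
#' @param groups named character vector mapping every sample label to its
#'   group (e.g. replicate to tissue).
#' @return A `count_matrix` object (list with `counts` and `groups`).
#' @export
count_matrix <- function(counts, groups) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0)) stop("negative count entries are not allowed")
  if (anyDuplicated(rownames(counts))) stop("duplicate transcript ids")
  missing <- setdiff(colnames(counts), names(groups))
  if (length(missing)) {
    stop("sample(s) missing from group map: ", paste(missing, collapse = ", "))
  }
  groups <- groups[colnames(counts)]
  structure(list(counts = counts, groups = groups), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " transcripts x ",
      ncol(x$counts), " samples (", length(unique(x$groups)),
      " groups)\n", sep = "")
  invisible(x)
}

#' Read a per-sample fragment count table
#'
#' @param path TSV with a header row of sample labels and a leading
#'   transcript-id column.
#' @param sample_groups named character vector mapping sample label to group.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, sample_groups) {
  tab <- utils::read.delim(path, header = TRUE, row.names = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  storage.mode(m) <- "numeric"
  if (anyNA(m)) stop("non-numeric count entries in ", path)
  count_matrix(m, sample_groups)
}

#' Write a count matrix to TSV
#' @param x a [count_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(transcript_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read rRNA predictions
#'
#' Tabular rRNA gene predictions on transcripts: columns `transcript_id`,
#' `start`, `end` (0-based half-open on the transcript) and `score`.
#'
#' @param path TSV path with header.
#' @return data.frame of predictions.
#' @export
read_rrna_predictions <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("transcript_id", "start", "end", "score")
  if (!all(need %in% names(tab))) {
    stop("rRNA prediction table must have columns: ",
         paste(need, collapse = ", "))
  }
  if (any(tab$start < 0) || any(tab$start >= tab$end)) {
    stop("rRNA prediction with start < 0 or start >= end in ", path)
  }
  tab[need]
}

#' Read a KEGG-orthology assignment table
#'
#' @param path TSV with header and columns `transcript_id`, `ko` and
#'   optionally `pathway`.
#' @return data.frame with those columns (`pathway` filled with `NA` when
#'   absent).
#' @export
read_ko_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "ko") %in% names(tab))) {
    stop("KO table must have columns transcript_id and ko")
  }
  if (is.null(tab$pathway)) tab$pathway <- NA_character_
  tab[c("transcript_id", "ko", "pathway")]
}

#' Read a pathway definition (enzyme label to KO ids)
#'
#' @param path TSV with header and columns `enzyme_label`, `ko`; one row per
#'   (label, KO) pair.
#' @return named list mapping enzyme label to a character vector of KO ids,
#'   in file order of first appearance.
#' @export
read_pathway_definition <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("enzyme_label", "ko") %in% names(tab))) {
    stop("pathway definition must have columns enzyme_label and ko")
  }
  split(tab$ko, factor(tab$enzyme_label, levels = unique(tab$enzyme_label)))
}
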