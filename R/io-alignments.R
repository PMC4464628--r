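#' Construct an alignment set
#'
#' One row per genome placement of a transcript. Coordinates are 0-based
#' half-open throughout the package; file dialects convert at the boundary.
#' A transcript aligned to several places contributes several rows.
#'
#' @param transcript_id character vector.
#' @param scaffold character vector of genomic sequence names.
#' @param strand character vector, `"+"` or `"-"`.
#' @param exons list of two-column numeric matrices (`start`, `end`),
#'   0-based half-open, sorted, non-overlapping.
#' @param identity_pct,coverage_pct numeric vectors in \[0, 100\].
#' @return An `alignment_set` data.frame with the above columns plus the
#'   derived `span_start`/`span_end` (union span of the exon blocks).
#' @export
alignment_set <- function(transcript_id, scaffold, strand, exons,
                          identity_pct, coverage_pct) {
  n <- length(transcript_id)
  stopifnot(length(scaffold) == n, length(strand) == n,
            length(exons) == n, length(identity_pct) == n,
            length(coverage_pct) == n,
            all(strand %in% c("+", "-")),
            all(identity_pct >= 0 & identity_pct <= 100),
            all(coverage_pct >= 0 & coverage_pct <= 100))
  exons <- lapply(seq_len(n), function(i) {
    b <- exons[[i]]
    stopifnot(is.matrix(b), ncol(b) == 2L, nrow(b) >= 1L)
    if (is.unsorted(b[, 1L])) {
      warning("unsorted exon blocks for ", transcript_id[i],
              "; sorting silently")
      b <- b[order(b[, 1L]), , drop = FALSE]
    }
    if (any(b[, 1L] >= b[, 2L])) {
      stop("degenerate exon block (start >= end) for ", transcript_id[i])
    }
    if (nrow(b) > 1L && any(b[-1L, 1L] < b[-nrow(b), 2L])) {
      stop("overlapping exon blocks for ", transcript_id[i])
    }
    dimnames(b) <- list(NULL, c("start", "end"))
    b
  })
  out <- data.frame(transcript_id = transcript_id, scaffold = scaffold,
                    strand = strand,
                    identity_pct = as.numeric(identity_pct),
                    coverage_pct = as.numeric(coverage_pct),
                    span_start = vapply(exons, function(b) b[1L, 1L], 0),
                    span_end = vapply(exons, function(b) b[nrow(b), 2L], 0),
                    stringsAsFactors = FALSE)
  out$exons <- exons
  class(out) <- c("alignment_set", "data.frame")
  out
}

#' Read transcript-to-genome alignments from GMAP-style GFF3
#'
#' Consumes the GMAP gene-structure GFF3 dialect: `mRNA` features carry the
#' transcript id (`Name`, falling back to `ID`) plus `identity` and
#' `coverage` attributes in percent; `exon` features reference their mRNA
#' through `Parent`. GFF3 1-based inclusive coordinates are converted to the
#' internal 0-based half-open convention. Placements are screened against the
#' identity/coverage thresholds here; the policy for choosing among multiple
#' retained placements of one transcript lives in [cluster_by_locus()].
#'
#' @param path GFF3 file path.
#' @param min_identity,min_coverage acceptance thresholds in percent. The
#'   identity default matches the usual GMAP screening value of 95; coverage
#'   defaults to 90.
#' @return A list with `accepted` (an [alignment_set()]) and `rejected_ids`
#'   (ids of placements failing the thresholds).
#' @export
read_alignments_gff3 <- function(path, min_identity = 95, min_coverage = 90) {
  gff <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "start", "end", "strand", "type"),
    tags = c("ID", "Name", "Parent", "identity", "coverage")))
  mrna <- gff[gff$type == "mRNA", , drop = FALSE]
  exon <- gff[gff$type == "exon", , drop = FALSE]
  parents <- as.character(unlist(exon$Parent))
  if (nrow(exon) > 0L &&
      (length(parents) != nrow(exon) || !all(parents %in% mrna$ID))) {
    stop("exon feature with no parent mRNA in ", path)
  }
  if (nrow(mrna) == 0L) {
    return(list(accepted = alignment_set(character(0), character(0),
                                         character(0), list(),
                                         numeric(0), numeric(0)),
                rejected_ids = character(0)))
  }
  tid <- ifelse(is.na(mrna$Name) | !nzchar(mrna$Name), mrna$ID, mrna$Name)
  identity <- as.numeric(mrna$identity)
  coverage <- as.numeric(mrna$coverage)
  if (anyNA(identity) || anyNA(coverage)) {
    stop("mRNA feature(s) missing identity/coverage attributes")
  }
  keep <- identity >= min_identity & coverage >= min_coverage
  rejected <- unique(tid[!keep])
  idx <- which(keep)
  blocks <- lapply(idx, function(i) {
    e <- exon[parents == mrna$ID[i], , drop = FALSE]
    if (nrow(e) == 0L) stop("mRNA ", tid[i], " has no exon features")
    cbind(start = e$start - 1, end = as.numeric(e$end))  # 1-based incl -> half-open
  })
  acc <- alignment_set(tid[idx], as.character(mrna$seqid[idx]),
                       as.character(mrna$strand[idx]), blocks,
                       identity[idx], coverage[idx])
  list(accepted = acc, rejected_ids = rejected)
}

#' Write an alignment set as GMAP-style GFF3
#'
#' Inverse of [read_alignments_gff3()] (converts back to 1-based inclusive
#' coordinates); used by the fixture generator and for export.
#'
#' @param x an [alignment_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments_gff3 <- function(x, path) {
  stopifnot(inherits(x, "alignment_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(x))) {
    mid <- sprintf("%s.path%d", x$transcript_id[i], i)
    writeLines(sprintf(
      "%s\tnrunigene\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;identity=%.1f;coverage=%.1f",
      x$scaffold[i], x$span_start[i] + 1L, x$span_end[i], x$strand[i],
      mid, x$transcript_id[i], x$identity_pct[i], x$coverage_pct[i]), con)
    b <- x$exons[[i]]
    for (j in seq_len(nrow(b))) {
      writeLines(sprintf(
        "%s\tnrunigene\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        x$scaffold[i], b[j, 1L] + 1L, b[j, 2L], x$strand[i], mid, j, mid),
        con)
    }
  }
  invisible(path)
}
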