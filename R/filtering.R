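#' Remove transcripts with strong contaminant-database hits
#'
#' De novo assemblies of field-grown plant tissue routinely contain
#' microbial transcripts. A transcript is removed when at least one hit
#' against the contaminant database satisfies all three thresholds:
#' `evalue <= max_evalue`, `identity_pct >= min_identity`, and aligned
#' length covering at least `min_covered_fraction` of the transcript.
#'
#' @param transcripts a [transcript_set()].
#' @param hits data.frame from [read_hits_table()] (transcript vs
#'   contaminant database; `query_id` is the transcript).
#' @param max_evalue,min_identity,min_covered_fraction removal thresholds.
#' @return list with `kept` (a transcript_set) and `removed_ids`.
#' @export
filter_contaminants <- function(transcripts, hits, max_evalue = 1e-10,
                                min_identity = 90,
                                min_covered_fraction = 0.5) {
  stopifnot(inherits(transcripts, "transcript_set"))
  removed <- character(0)
  if (!is.null(hits) && nrow(hits) > 0L) {
    unknown <- !(hits$query_id %in% transcripts$id)
    if (any(unknown)) {
      warning("ignoring ", sum(unknown),
              " hit(s) referencing unknown transcript id(s)")
      hits <- hits[!unknown, , drop = FALSE]
    }
    tlen <- transcripts$length[match(hits$query_id, transcripts$id)]
    bad <- hits$evalue <= max_evalue &
      hits$identity_pct >= min_identity &
      hits$align_len / tlen >= min_covered_fraction
    removed <- unique(hits$query_id[bad])
  }
  list(kept = transcripts[!(transcripts$id %in% removed), , drop = FALSE],
       removed_ids = removed)
}

#' Remove transcripts dominated by predicted rRNA
#'
#' A transcript is removed when the union of its predicted rRNA intervals
#' covers at least `min_rrna_fraction` of its length. Partial rRNA fragments
#' in UTR-like regions therefore do not trigger removal at the default.
#'
#' @param transcripts a [transcript_set()].
#' @param predictions data.frame from [read_rrna_predictions()].
#' @param min_rrna_fraction covered-fraction threshold in \[0, 1\].
#' @return list with `kept` and `removed_ids`.
#' @export
filter_rrna <- function(transcripts, predictions, min_rrna_fraction = 0.5) {
  stopifnot(inherits(transcripts, "transcript_set"))
  removed <- character(0)
  if (nrow(predictions) > 0L) {
    tlen <- transcripts$length[match(predictions$transcript_id,
                                     transcripts$id)]
    if (anyNA(tlen)) {
      stop("rRNA prediction for unknown transcript id: ",
           predictions$transcript_id[which(is.na(tlen))[1L]])
    }
    if (any(predictions$end > tlen)) {
      stop("rRNA prediction out of transcript bounds for ",
           predictions$transcript_id[which(predictions$end > tlen)[1L]])
    }
    cov <- vapply(split(predictions, predictions$transcript_id), function(p) {
      r <- IRanges::reduce(IRanges::IRanges(start = p$start + 1L,
                                            end = p$end))
      sum(IRanges::width(r))
    }, 0)
    frac <- cov / transcripts$length[match(names(cov), transcripts$id)]
    removed <- names(cov)[frac >= min_rrna_fraction]
  }
  list(kept = transcripts[!(transcripts$id %in% removed), , drop = FALSE],
       removed_ids = removed)
}

#' Flag putative long noncoding transcripts
#'
#' A transcript is flagged as lncRNA when it has no ORF of at least
#' `min_orf_aa` amino acids and no protein-database hit at or below
#' `max_evalue`. This is a deliberately simple, testable coding-evidence
#' rule (long ORF or protein homology); coding-potential scoring models are
#' out of scope.
#'
#' @param transcripts a [transcript_set()].
#' @param orf_annotations data.frame from [classify_orf_set()]'s `orfs`
#'   element (or [find_best_orf()] rows); only transcripts present there are
#'   considered to have an ORF.
#' @param protein_hits data.frame from [read_hits_table()] (vs a protein
#'   database), or `NULL` for none.
#' @param min_orf_aa minimum ORF length in amino acids.
#' @param max_evalue homology-evidence threshold.
#' @return character vector of flagged transcript ids.
#' @export
flag_noncoding <- function(transcripts, orf_annotations, protein_hits = NULL,
                           min_orf_aa = 100, max_evalue = 1e-5) {
  stopifnot(inherits(transcripts, "transcript_set"))
  has_orf <- character(0)
  if (!is.null(orf_annotations) && nrow(orf_annotations) > 0L) {
    ok <- orf_annotations$aa_length >= min_orf_aa
    has_orf <- unique(orf_annotations$transcript_id[ok])
  }
  has_hom <- character(0)
  if (!is.null(protein_hits) && nrow(protein_hits) > 0L) {
    has_hom <- unique(protein_hits$query_id[protein_hits$evalue <= max_evalue])
  }
  setdiff(transcripts$id, union(has_orf, has_hom))
}

#' Run the post-assembly cleanup cascade
#'
#' Applies the three removal stages in order contaminant -> rRNA -> lncRNA.
#' Each removed transcript is attributed to the first stage that removed it,
#' so the report categories partition the removed set.
#'
#' @param transcripts a [transcript_set()].
#' @param contaminant_hits,protein_hits hit tables ([read_hits_table()]);
#'   `NULL` or empty for none.
#' @param rrna_predictions prediction table ([read_rrna_predictions()]);
#'   `NULL` or empty for none.
#' @param config named list of stage thresholds; any of `max_evalue`,
#'   `min_identity`, `min_covered_fraction`, `min_rrna_fraction`,
#'   `min_orf_aa`, `protein_max_evalue` override the stage defaults.
#' @return list with `kept` (filtered transcript_set) and `report`
#'   (a `filter_report`).
#' @export
run_filter_cascade <- function(transcripts, contaminant_hits = NULL,
                               rrna_predictions = NULL, protein_hits = NULL,
                               config = list()) {
  stopifnot(inherits(transcripts, "transcript_set"))
  cfg <- utils::modifyList(list(max_evalue = 1e-10, min_identity = 90,
                                min_covered_fraction = 0.5,
                                min_rrna_fraction = 0.5, min_orf_aa = 100,
                                protein_max_evalue = 1e-5), config)
  n0 <- nrow(transcripts)
  if (n0 == 0L) stop("empty transcript set")

  empty_hits <- read_hits_table(textConnection_empty())
  s1 <- filter_contaminants(transcripts,
                            contaminant_hits %||% empty_hits,
                            cfg$max_evalue, cfg$min_identity,
                            cfg$min_covered_fraction)
  preds <- rrna_predictions %||%
    data.frame(transcript_id = character(0), start = integer(0),
               end = integer(0), score = numeric(0))
  s2 <- filter_rrna(s1$kept, preds[preds$transcript_id %in% s1$kept$id, ,
                                   drop = FALSE],
                    cfg$min_rrna_fraction)
  orfs <- classify_orf_set(s2$kept, min_orf_aa = cfg$min_orf_aa)$orfs
  lnc <- flag_noncoding(s2$kept, orfs, protein_hits,
                        cfg$min_orf_aa, cfg$protein_max_evalue)
  kept <- s2$kept[!(s2$kept$id %in% lnc), , drop = FALSE]

  report <- structure(list(
    initial_count = n0,
    removed_contaminant = length(s1$removed_ids),
    removed_rrna = length(s2$removed_ids),
    removed_lncrna = length(lnc),
    final_count = nrow(kept),
    removed_fraction = 1 - nrow(kept) / n0,
    removed_ids = list(contaminant = s1$removed_ids, rrna = s2$removed_ids,
                       lncrna = lnc)),
    class = "filter_report")
  list(kept = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n",
      "  initial:      ", x$initial_count, "\n",
      "  contaminant:  -", x$removed_contaminant, "\n",
      "  rRNA:         -", x$removed_rrna, "\n",
      "  lncRNA:       -", x$removed_lncrna, "\n",
      "  final:        ", x$final_count,
      sprintf("  (%.1f%% removed)\n", 100 * x$removed_fraction), sep = "")
  invisible(x)
}

#' Write a filter report as TSV
#' @param x a `filter_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(x, path) {
  stopifnot(inherits(x, "filter_report"))
  df <- data.frame(
    metric = c("initial_count", "removed_contaminant", "removed_rrna",
               "removed_lncrna", "final_count", "removed_fraction"),
    value = c(x$initial_count, x$removed_contaminant, x$removed_rrna,
              x$removed_lncrna, x$final_count, x$removed_fraction))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# An empty 12-column hits connection for stage defaults.
textConnection_empty <- function() textConnection(character(0))
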