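#' Identify UDP-glycosyltransferase candidates by motif (and homology)
#'
#' Scans the peptide of every unigene for the plant secondary product
#' glycosyltransferase (PSPG) signature supplied as a PROSITE pattern.
#' The peptide is the best-ORF translation when one was reported;
#' transcripts without a reported ORF fall back to all six frame
#' translations. Optionally, homology evidence against a reference UGT
#' set (hit table with `evalue <= max_evalue`) also qualifies a
#' transcript, so adding a homology table never removes candidates.
#'
#' @param transcripts a [transcript_set()] (the Nr unigene set).
#' @param orfs ORF table from [classify_orf_set()] (may cover a subset).
#' @param pattern PROSITE pattern string or `prosite_pattern`.
#' @param homology_hits optional [read_hits_table()] table vs a reference
#'   UGT collection (`query_id` = transcript id).
#' @param max_evalue homology threshold (default 1e-5).
#' @return data.frame of candidates: `transcript_id`, `evidence`
#'   (`"motif"`, `"homology"` or `"both"`), `n_motif_hits`.
#' @export
identify_ugt_candidates <- function(transcripts, orfs, pattern,
                                    homology_hits = NULL,
                                    max_evalue = 1e-5) {
  stopifnot(inherits(transcripts, "transcript_set"))
  if (is.character(pattern)) pattern <- parse_prosite(pattern)
  motif_hits <- integer(0)
  for (i in seq_len(nrow(transcripts))) {
    id <- transcripts$id[i]
    row <- if (!is.null(orfs)) orfs[orfs$transcript_id == id, , drop = FALSE]
    peps <- if (!is.null(row) && nrow(row) > 0L) row$peptide[1L]
            else translate_six_frames(transcripts$sequence[i])
    nh <- sum(vapply(peps, function(p) nrow(scan_protein(pattern, p)), 0L))
    if (nh > 0L) motif_hits[id] <- nh
  }
  hom_ids <- character(0)
  if (!is.null(homology_hits) && nrow(homology_hits) > 0L) {
    hom_ids <- intersect(
      unique(homology_hits$query_id[homology_hits$evalue <= max_evalue]),
      transcripts$id)
  }
  ids <- union(names(motif_hits), hom_ids)
  if (!length(ids)) {
    return(data.frame(transcript_id = character(0), evidence = character(0),
                      n_motif_hits = integer(0), stringsAsFactors = FALSE))
  }
  ids <- transcripts$id[transcripts$id %in% ids]  # input order
  evidence <- ifelse(ids %in% names(motif_hits),
                     ifelse(ids %in% hom_ids, "both", "motif"), "homology")
  data.frame(transcript_id = ids, evidence = evidence,
             n_motif_hits = ifelse(is.na(motif_hits[ids]), 0L,
                                   motif_hits[ids]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Group pathway transcripts by enzyme from KEGG-orthology assignments
#'
#' @param ko_table data.frame from [read_ko_table()] (transcript -> KO).
#' @param pathway_definition named list, enzyme label -> character vector
#'   of KO ids ([read_pathway_definition()]); every label needs >= 1 KO.
#' @return A `pathway_groups` data.frame: `enzyme_label`, `ko_ids`
#'   (comma-joined), `member_transcripts` (list column) and `copy_count`
#'   (distinct transcripts per enzyme); the total number of distinct
#'   (transcript, enzyme) assignments is in attribute `total_transcripts`.
#'   Transcripts matching no pathway KO are ignored.
#' @export
group_pathway_genes <- function(ko_table, pathway_definition) {
  stopifnot(is.list(pathway_definition), length(pathway_definition) >= 1L)
  if (any(lengths(pathway_definition) == 0L)) {
    stop("enzyme label(s) with no KO ids: ",
         paste(names(pathway_definition)[lengths(pathway_definition) == 0L],
               collapse = ", "))
  }
  labels <- names(pathway_definition)
  members <- lapply(labels, function(lab) {
    sort(unique(
      ko_table$transcript_id[ko_table$ko %in% pathway_definition[[lab]]]),
      method = "radix")
  })
  out <- data.frame(
    enzyme_label = labels,
    ko_ids = vapply(pathway_definition, paste, character(1), collapse = ","),
    copy_count = lengths(members),
    stringsAsFactors = FALSE, row.names = NULL)
  out$member_transcripts <- members
  attr(out, "total_transcripts") <- sum(lengths(members))
  class(out) <- c("pathway_groups", "data.frame")
  out
}

#' @export
print.pathway_groups <- function(x, ...) {
  cat("<pathway_groups> ", nrow(x), " enzymes, ",
      attr(x, "total_transcripts"), " transcript assignments (",
      sum(x$copy_count > 1L), " enzymes in multiple copies)\n", sep = "")
  invisible(x)
}

#' Write pathway groups as TSV
#' @param x a `pathway_groups` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pathway_groups_tsv <- function(x, path) {
  df <- data.frame(enzyme_label = x$enzyme_label, ko_ids = x$ko_ids,
                   copy_count = x$copy_count,
                   member_transcripts = vapply(x$member_transcripts, paste,
                                               character(1), collapse = ","),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
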