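#' Cluster genome-aligned transcripts into gene loci
#'
#' Single-linkage clustering of alignment spans per scaffold (and strand,
#' when `strand_aware`): two placements are linked when their spans overlap
#' by at least `min_overlap_bp`; locus clusters are the connected
#' components. Overlap is span-based (intron-spanning), reflecting
#' clustering by gene locus rather than by shared exonic bases.
#'
#' A transcript with retained placements in several components is assigned
#' to the component containing its best placement (highest identity, then
#' longest span, then lexicographically smallest scaffold and smallest
#' start); components left without any assigned transcript are dropped.
#'
#' @param alignments an [alignment_set()], already screened by
#'   identity/coverage at read time.
#' @param strand_aware cluster per strand (default) so antisense overlapping
#'   genes stay distinct; `FALSE` merges strands.
#' @param min_overlap_bp minimum span overlap linking two placements.
#' @return data.frame of clusters: `cluster_id`, `scaffold`, `strand`
#'   (`"merged"` when not strand-aware), `start`, `end` (footprint,
#'   half-open), `member_ids` (list column), `representative_id`
#'   (`NA` until [select_representative()]).
#' @export
cluster_by_locus <- function(alignments, strand_aware = TRUE,
                             min_overlap_bp = 1L) {
  stopifnot(inherits(alignments, "alignment_set"), min_overlap_bp >= 1L)
  empty <- data.frame(cluster_id = character(0), scaffold = character(0),
                      strand = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  empty$member_ids <- list()
  empty$representative_id <- character(0)
  if (nrow(alignments) == 0L) return(empty)

  aln <- as.data.frame(alignments[c("transcript_id", "scaffold", "strand",
                                    "identity_pct", "span_start",
                                    "span_end")])
  aln$strand_key <- if (strand_aware) aln$strand else "merged"
  aln$row <- seq_len(nrow(aln))

  # Sweep per (scaffold, strand) over starts. Spans shorter than the
  # overlap threshold can never link to anything and are isolated
  # immediately; a long span joins the open component iff the component's
  # max end reaches at least min_overlap_bp past the span's start (the
  # qualifying threshold start + min_overlap_bp only grows with the sweep,
  # so a component that fails once can be closed for good).
  aln <- aln[order(aln$scaffold, aln$strand_key, aln$span_start,
                   aln$span_end, method = "radix"), , drop = FALSE]
  comp <- integer(nrow(aln))
  cur <- 0L
  active <- NA_integer_
  cur_end <- -Inf
  cur_key <- ""
  for (i in seq_len(nrow(aln))) {
    key <- paste0(aln$scaffold[i], "\r", aln$strand_key[i])
    if (key != cur_key) {
      active <- NA_integer_
      cur_end <- -Inf
      cur_key <- key
    }
    s <- aln$span_start[i]
    e <- aln$span_end[i]
    if (e - s < min_overlap_bp) {        # too short to link either way
      cur <- cur + 1L
      comp[i] <- cur
      next
    }
    if (!is.na(active) && cur_end >= s + min_overlap_bp) {
      comp[i] <- active
      cur_end <- max(cur_end, e)
    } else {
      cur <- cur + 1L
      active <- cur
      comp[i] <- cur
      cur_end <- e
    }
  }
  aln$component <- comp

  # Best placement per transcript decides its cluster membership.
  ord <- order(aln$transcript_id, -aln$identity_pct,
               -(aln$span_end - aln$span_start), aln$scaffold,
               aln$span_start, method = "radix")
  best <- aln[ord, , drop = FALSE]
  best <- best[!duplicated(best$transcript_id), , drop = FALSE]
  home <- best$component
  names(home) <- best$transcript_id
  owned <- aln[home[aln$transcript_id] == aln$component, , drop = FALSE]

  comps <- split(owned, owned$component)
  clusters <- do.call(rbind, lapply(comps, function(g) {
    data.frame(scaffold = g$scaffold[1L], strand = g$strand_key[1L],
               start = min(g$span_start), end = max(g$span_end),
               stringsAsFactors = FALSE)
  }))
  ord2 <- order(clusters$scaffold, clusters$strand, clusters$start,
                method = "radix")
  clusters <- clusters[ord2, , drop = FALSE]
  members <- lapply(comps, function(g) sort(unique(g$transcript_id)))[ord2]
  out <- data.frame(cluster_id = sprintf("locus_%05d",
                                         seq_len(nrow(clusters))),
                    clusters, stringsAsFactors = FALSE)
  out$member_ids <- members
  out$representative_id <- NA_character_
  rownames(out) <- NULL
  out
}

#' Select the representative transcript of a locus cluster
#'
#' The longest member is the unigene representative; ties break to the
#' lexicographically smallest id (C locale) for reproducibility.
#'
#' @param member_ids character vector of member transcript ids.
#' @param transcripts a [transcript_set()] resolving every member.
#' @return the representative transcript id.
#' @export
select_representative <- function(member_ids, transcripts) {
  stopifnot(length(member_ids) >= 1L)
  idx <- match(member_ids, transcripts$id)
  if (anyNA(idx)) {
    stop("unknown member id(s): ",
         paste(member_ids[is.na(idx)], collapse = ", "))
  }
  len <- transcripts$length[idx]
  cand <- member_ids[len == max(len)]
  sort(cand, method = "radix")[1L]
}

#' Collapse unaligned transcripts by assembler component
#'
#' Transcripts without a genome placement are grouped by their assembler
#' component id (isoform group); the longest member of each component is
#' kept (tie: lexicographically smallest id). Ids without an isoform suffix
#' form singleton components.
#'
#' @param unaligned a [transcript_set()] of unaligned transcripts.
#' @return character vector of representative ids (one per component),
#'   sorted.
#' @export
collapse_unaligned <- function(unaligned) {
  stopifnot(inherits(unaligned, "transcript_set"))
  if (nrow(unaligned) == 0L) return(character(0))
  reps <- vapply(split(seq_len(nrow(unaligned)), unaligned$component_id),
                 function(ix) {
                   len <- unaligned$length[ix]
                   cand <- unaligned$id[ix][len == max(len)]
                   sort(cand, method = "radix")[1L]
                 }, character(1))
  sort(unname(reps), method = "radix")
}

#' Summary statistics of an assembly
#'
#' @param lengths integer vector of sequence lengths (all >= 1).
#' @return list with `count`, `max_len`, `mean_len` (rounded to nearest
#'   integer) and `n50` (smallest member length L such that sequences of
#'   length >= L contain at least half the total bases).
#' @export
assembly_stats <- function(lengths) {
  if (length(lengths) == 0L) stop("assembly_stats: empty length set")
  stopifnot(all(lengths >= 1))
  sorted <- sort(lengths, decreasing = TRUE)
  n50 <- sorted[which(cumsum(as.numeric(sorted)) >= sum(as.numeric(sorted)) / 2)[1L]]
  list(count = length(lengths), max_len = max(lengths),
       mean_len = as.integer(round(mean(lengths))), n50 = as.integer(n50))
}

#' Build the non-redundant unigene set
#'
#' The core redundancy-reduction step: transcripts with at least one
#' retained genome placement are clustered into loci
#' ([cluster_by_locus()]) and each locus contributes its longest member;
#' transcripts with no placement are collapsed per assembler component
#' ([collapse_unaligned()]). The union of the two representative sets is
#' the non-redundant (Nr) unigene set.
#'
#' @param filtered_transcripts a [transcript_set()] surviving the filter
#'   cascade.
#' @param alignments an [alignment_set()] of retained placements (ids not
#'   present in `filtered_transcripts` are ignored).
#' @param strand_aware,min_overlap_bp passed to [cluster_by_locus()].
#' @return An `nr_unigene_set`: list with `representatives` (transcript_set),
#'   `source_of` (named character, `"aligned_locus"` or
#'   `"unaligned_component"`), `clusters` (the locus table with
#'   representatives filled in), `representative_of` (named character mapping
#'   every input transcript to its representative), `n_loci`,
#'   `n_unaligned_components` and `stats` ([assembly_stats()] over
#'   representative lengths).
#' @export
build_unigene_set <- function(filtered_transcripts, alignments,
                              strand_aware = TRUE, min_overlap_bp = 1L) {
  stopifnot(inherits(filtered_transcripts, "transcript_set"))
  aln <- alignments[alignments$transcript_id %in% filtered_transcripts$id, ,
                    drop = FALSE]
  clusters <- cluster_by_locus(aln, strand_aware, min_overlap_bp)
  if (nrow(clusters) > 0L) {
    clusters$representative_id <- vapply(
      clusters$member_ids, select_representative, character(1),
      transcripts = filtered_transcripts)
  }
  aligned_ids <- unique(unlist(clusters$member_ids))
  unaligned <- filtered_transcripts[
    !(filtered_transcripts$id %in% aligned_ids), , drop = FALSE]
  un_reps <- collapse_unaligned(unaligned)

  rep_ids <- c(clusters$representative_id, un_reps)
  source_of <- c(rep("aligned_locus", nrow(clusters)),
                 rep("unaligned_component", length(un_reps)))
  names(source_of) <- rep_ids

  rep_of <- character(nrow(filtered_transcripts))
  names(rep_of) <- filtered_transcripts$id
  for (i in seq_len(nrow(clusters))) {
    rep_of[clusters$member_ids[[i]]] <- clusters$representative_id[i]
  }
  if (nrow(unaligned) > 0L) {
    comp_rep <- vapply(split(seq_len(nrow(unaligned)),
                             unaligned$component_id),
                       function(ix) {
                         len <- unaligned$length[ix]
                         cand <- unaligned$id[ix][len == max(len)]
                         sort(cand, method = "radix")[1L]
                       }, character(1))
    rep_of[unaligned$id] <- comp_rep[unaligned$component_id]
  }

  reps <- filtered_transcripts[match(rep_ids, filtered_transcripts$id), ,
                               drop = FALSE]
  structure(list(representatives = reps, source_of = source_of,
                 clusters = clusters, representative_of = rep_of,
                 n_loci = nrow(clusters),
                 n_unaligned_components = length(un_reps),
                 stats = assembly_stats(reps$length)),
            class = "nr_unigene_set")
}

#' @export
print.nr_unigene_set <- function(x, ...) {
  s <- x$stats
  cat("<nr_unigene_set> ", s$count, " unigenes (",
      x$n_loci, " loci + ", x$n_unaligned_components,
      " unaligned components)\n", sep = "")
  cat(sprintf("  max %d bp, mean %d bp, N50 %d bp\n",
              s$max_len, s$mean_len, s$n50))
  invisible(x)
}

#' Write a locus cluster table as TSV
#' @param clusters cluster table from [cluster_by_locus()] /
#'   [build_unigene_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters_tsv <- function(clusters, path) {
  df <- data.frame(cluster_id = clusters$cluster_id,
                   scaffold = clusters$scaffold, strand = clusters$strand,
                   start = clusters$start, end = clusters$end,
                   member_ids = vapply(clusters$member_ids, paste,
                                       character(1), collapse = ","),
                   representative_id = clusters$representative_id,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
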