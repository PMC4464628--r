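# Codon -> amino acid (standard code); codons containing ambiguity become X.
translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

frame_views <- function(sequence) {
  rc <- revcomp(sequence)
  list(
    list(label = "+1", rank = 1L, seq = sequence, offset = 0L, rev = FALSE),
    list(label = "+2", rank = 2L, seq = sequence, offset = 1L, rev = FALSE),
    list(label = "+3", rank = 3L, seq = sequence, offset = 2L, rev = FALSE),
    list(label = "-1", rank = 4L, seq = rc, offset = 0L, rev = TRUE),
    list(label = "-2", rank = 5L, seq = rc, offset = 1L, rev = TRUE),
    list(label = "-3", rank = 6L, seq = rc, offset = 2L, rev = TRUE))
}

frame_codons <- function(fr) {
  n_cod <- (nchar(fr$seq) - fr$offset) %/% 3L
  if (n_cod <= 0L) return(character(0))
  st <- fr$offset + 3L * (seq_len(n_cod) - 1L) + 1L
  substring(fr$seq, st, st + 2L)
}

#' Find the best open reading frame of a transcript
#'
#' Scans all six frames. Candidate ORFs are maximal runs of non-stop codons
#' that begin either at an ATG or at the frame's 5' edge and end either at
#' a stop codon (TAA/TAG/TGA) or at the frame's 3' edge; runs that begin
#' right after a stop without an ATG are not candidates. Codons containing
#' ambiguity symbols never match start or stop. The reported ORF is the
#' candidate with the most amino acids at or above `min_orf_aa`
#' (ties: frame order +1, +2, +3, -1, -2, -3, then 5'-most within the
#' frame). The amino-acid length excludes the stop codon.
#'
#' Completeness relative to the transcript edges: `complete` (start and
#' stop), `five_prime_partial` (stop only), `three_prime_partial` (start
#' only), `internal` (neither).
#'
#' @param transcript one row of a [transcript_set()] (or any list with
#'   `id` and `sequence`).
#' @param min_orf_aa minimum protein length in amino acids (default 100).
#' @return A one-row data.frame (`transcript_id`, `frame`, `start`, `end`
#'   0-based half-open on the forward transcript, `aa_length`,
#'   `has_start_codon`, `has_stop_codon`, `category`, `peptide`), or `NULL`
#'   when no candidate reaches `min_orf_aa`.
#' @export
find_best_orf <- function(transcript, min_orf_aa = 100L) {
  s <- toupper(transcript$sequence[[1L]])
  id <- transcript$id[[1L]]
  L <- nchar(s)
  if (L < 3L * min_orf_aa) return(NULL)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (fr in frame_views(s)) {
    codons <- frame_codons(fr)
    n_cod <- length(codons)
    if (n_cod < min_orf_aa) next
    stop_at <- which(codons %in% stops)
    seg_start <- c(1L, stop_at + 1L)
    seg_end <- c(stop_at - 1L, n_cod)
    for (k in seq_along(seg_start)) {
      a <- seg_start[k]
      b <- seg_end[k]
      if (b < a) next
      terminated <- k <= length(stop_at)
      starts <- integer(0)
      if (a == 1L) starts <- 1L                      # frame-edge candidate
      atg <- which(codons[a:b] == "ATG")
      if (length(atg)) {
        m <- a + atg[1L] - 1L
        if (!(a == 1L && m == 1L)) starts <- c(starts, m)
      }
      for (st in starts) {
        aa <- b - st + 1L
        if (aa < min_orf_aa) next
        cand <- list(rank = fr$rank, frame = fr$label, start_codon = st,
                     end_codon = b, aa = aa,
                     has_start = codons[st] == "ATG",
                     has_stop = terminated,
                     offset = fr$offset, rev = fr$rev)
        if (is.null(best) ||
            cand$aa > best$aa ||
            (cand$aa == best$aa &&
             (cand$rank < best$rank ||
              (cand$rank == best$rank && cand$start_codon < best$start_codon)))) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  nt_start_f <- best$offset + 3L * (best$start_codon - 1L)
  nt_end_f <- best$offset + 3L * best$end_codon + if (best$has_stop) 3L else 0L
  if (best$rev) {
    start <- L - nt_end_f
    end <- L - nt_start_f
  } else {
    start <- nt_start_f
    end <- nt_end_f
  }
  fr <- frame_views(s)[[best$rank]]
  codons <- frame_codons(fr)
  pep <- paste(translate_codons(codons[best$start_codon:best$end_codon]),
               collapse = "")
  category <- if (best$has_start && best$has_stop) "complete"
  else if (!best$has_start && best$has_stop) "five_prime_partial"
  else if (best$has_start && !best$has_stop) "three_prime_partial"
  else "internal"
  data.frame(transcript_id = id, frame = best$frame, start = start,
             end = end, aa_length = best$aa,
             has_start_codon = best$has_start,
             has_stop_codon = best$has_stop, category = category,
             peptide = pep, stringsAsFactors = FALSE)
}

#' Annotate and summarise ORFs over a transcript set
#'
#' @param transcripts a non-empty [transcript_set()].
#' @param min_orf_aa minimum protein length (default 100 aa).
#' @return list with `orfs` (row-bound [find_best_orf()] results for coding
#'   transcripts) and `summary`: `coding_fraction` (coding / total) and the
#'   four completeness fractions relative to coding transcripts (summing
#'   to 1).
#' @export
classify_orf_set <- function(transcripts, min_orf_aa = 100L) {
  stopifnot(inherits(transcripts, "transcript_set"))
  if (nrow(transcripts) == 0L) stop("classify_orf_set: empty transcript set")
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    find_best_orf(transcripts[i, , drop = FALSE], min_orf_aa)
  })
  orfs <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(orfs)) {
    orfs <- data.frame(transcript_id = character(0), frame = character(0),
                       start = integer(0), end = integer(0),
                       aa_length = integer(0), has_start_codon = logical(0),
                       has_stop_codon = logical(0), category = character(0),
                       peptide = character(0), stringsAsFactors = FALSE)
  }
  n <- nrow(transcripts)
  nc <- nrow(orfs)
  frac <- function(cat) if (nc == 0L) NA_real_ else mean(orfs$category == cat)
  list(orfs = orfs,
       summary = list(coding_fraction = nc / n,
                      fraction_complete = frac("complete"),
                      fraction_5partial = frac("five_prime_partial"),
                      fraction_3partial = frac("three_prime_partial"),
                      fraction_internal = frac("internal")))
}

#' Write an ORF annotation table as TSV
#' @param orfs the `orfs` table from [classify_orf_set()].
#' @param path output path.
#' @param peptides optional FASTA path for the encoded peptides.
#' @return `path`, invisibly.
#' @export
write_orfs_tsv <- function(orfs, path, peptides = NULL) {
  utils::write.table(
    orfs[c("transcript_id", "frame", "start", "end", "aa_length",
           "category")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(peptides)) {
    set <- Biostrings::BStringSet(orfs$peptide)
    names(set) <- orfs$transcript_id
    Biostrings::writeXStringSet(set, peptides)
  }
  invisible(path)
}

#' Six-frame translations of a nucleotide sequence
#'
#' Used as the peptide fallback for transcripts without a reported ORF
#' (e.g. when scanning for motifs). Stop codons appear as `*`, which no
#' pattern element matches, so motifs cannot span a stop.
#'
#' @param sequence nucleotide string.
#' @return named character vector of six peptides (`+1` .. `-3`).
#' @export
translate_six_frames <- function(sequence) {
  vapply(frame_views(toupper(sequence)), function(fr) {
    paste(translate_codons(frame_codons(fr)), collapse = "")
  }, character(1)) |>
    stats::setNames(c("+1", "+2", "+3", "-1", "-2", "-3"))
}
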