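#' Parse an assembler transcript identifier into component and isoform
#'
#' De novo assemblers emit isoform ids of the form `<component>_seq<k>`,
#' where the component names the assembly graph component (the putative
#' gene) and `k` indexes the isoform within it, e.g.
#' `"Pg_Root111466_c0_seq17"`. Ids that do not match the scheme (including
#' a `_seq0` suffix, since isoform indices start at 1) fall back to using
#' the whole id as the component.
#'
#' @param id character vector of transcript ids (non-empty strings).
#' @return A data.frame with columns `id`, `component_id` and
#'   `isoform_index` (`NA` when the id carries no isoform suffix).
#' @examples
#' parse_component_id("Pg_Root111466_c0_seq17")
#' parse_component_id(c("geneA", "x_seq0"))
#' @export
parse_component_id <- function(id) {
  stopifnot(is.character(id), all(nzchar(id)))
  m <- regmatches(id, regexec("^(.*)_seq([1-9][0-9]*)$", id))
  component <- id
  isoform <- rep(NA_integer_, length(id))
  hit <- lengths(m) == 3L
  if (any(hit)) {
    component[hit] <- vapply(m[hit], `[`, character(1), 2L)
    isoform[hit] <- as.integer(vapply(m[hit], `[`, character(1), 3L))
  }
  data.frame(id = id, component_id = component, isoform_index = isoform,
             stringsAsFactors = FALSE)
}

#' Construct a transcript set
#'
#' The central sequence container: a data.frame with one row per assembled
#' transcript carrying the uppercased nucleotide sequence, the parsed
#' assembler component id, the isoform index (or `NA`) and the sequence
#' length in bp.
#'
#' @param id character vector of unique transcript ids.
#' @param sequence character vector of nucleotide sequences (uppercased on
#'   construction; must be non-empty).
#' @return A `transcript_set` (data.frame subclass) with columns `id`,
#'   `sequence`, `component_id`, `isoform_index`, `length`.
#' @export
transcript_set <- function(id, sequence) {
  stopifnot(is.character(id), is.character(sequence),
            length(id) == length(sequence))
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate transcript id(s): ", paste(dup, collapse = ", "))
  }
  sequence <- toupper(sequence)
  if (any(!nzchar(sequence))) {
    stop("empty sequence for id(s): ",
         paste(id[!nzchar(sequence)], collapse = ", "))
  }
  bad <- grepl("[^ACGTUNRYSWKMBDHV]", sequence)
  if (any(bad)) {
    warning("non-IUPAC symbols kept verbatim in: ",
            paste(utils::head(id[bad], 5L), collapse = ", "))
  }
  parsed <- parse_component_id(id)
  out <- data.frame(id = id, sequence = sequence,
                    component_id = parsed$component_id,
                    isoform_index = parsed$isoform_index,
                    length = nchar(sequence), stringsAsFactors = FALSE)
  class(out) <- c("transcript_set", "data.frame")
  out
}

#' Read assembled transcripts from a FASTA file
#'
#' @param path path to a FASTA file. The id is the first whitespace-delimited
#'   token of each header; sequences are uppercased on read.
#' @return A [transcript_set()] in file order.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    return(transcript_set(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  transcript_set(ids, as.character(seqs))
}

#' Write a transcript set to FASTA
#'
#' @param x a [transcript_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "transcript_set"))
  set <- Biostrings::BStringSet(x$sequence)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("<transcript_set> ", nrow(x), " transcripts, total ",
      sum(x$length), " bp\n", sep = "")
  invisible(x)
}

# Reverse complement (IUPAC-aware, total: unknown symbols map to themselves
# so sequences kept verbatim by read_fasta still round-trip).
revcomp <- function(s) {
  vapply(s, function(x) {
    flipped <- chartr("ACGTUNRYSWKMBDHVacgtunryswkmbdhv",
                      "TGCAANYRSWMKVHDBtgcaanyrswmkvhdb", x)
    paste(rev(strsplit(flipped, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
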