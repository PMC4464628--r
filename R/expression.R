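#' Compute FPKM and group means from fragment counts
#'
#' `FPKM[t, s] = count[t, s] / ((length[t] / 1e3) * (libsize[s] / 1e6))`,
#' with `libsize[s]` the column sum of the count matrix. The effective
#' length is the transcript length (no fragment-length correction).
#'
#' @param counts a [count_matrix()].
#' @param effective_lengths named numeric vector, transcript id -> bp
#'   (must cover every transcript; all positive).
#' @return An `expression_table`: list with `counts`, `effective_lengths`,
#'   `fpkm` (transcript x sample), `group_means` (transcript x group,
#'   arithmetic means of replicate FPKM columns) and `groups`.
#' @export
compute_fpkm <- function(counts, effective_lengths) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  len <- effective_lengths[rownames(m)]
  if (anyNA(len)) {
    stop("missing effective length for: ",
         paste(utils::head(rownames(m)[is.na(len)], 5L), collapse = ", "))
  }
  if (any(len <= 0)) stop("effective lengths must be positive")
  libsize <- colSums(m)
  if (any(libsize <= 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(m)[libsize <= 0], collapse = ", "))
  }
  fpkm <- sweep(m / (len / 1e3), 2L, libsize / 1e6, "/")
  groups <- counts$groups
  glev <- unique(groups)
  group_means <- vapply(glev, function(g) {
    rowMeans(fpkm[, groups == g, drop = FALSE])
  }, numeric(nrow(m)))
  if (is.null(dim(group_means))) {
    group_means <- matrix(group_means, ncol = length(glev),
                          dimnames = list(rownames(m), glev))
  }
  structure(list(counts = counts, effective_lengths = len, fpkm = fpkm,
                 group_means = group_means, groups = groups),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat("<expression_table> ", nrow(x$fpkm), " transcripts x ",
      ncol(x$fpkm), " samples, groups: ",
      paste(colnames(x$group_means), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Call tissue-specific transcripts from group-mean FPKM
#'
#' A transcript is specific to a group when its group-mean FPKM is strictly
#' greater than `hi` there and strictly less than `lo` in every other
#' group. With `hi >= lo` at most one group can qualify.
#'
#' @param table an [compute_fpkm()] expression_table (needs >= 2 groups).
#' @param hi,lo FPKM thresholds (defaults 3 and 1).
#' @return data.frame with `transcript_id` and `specific_in` (group label
#'   or `NA`).
#' @export
call_specific <- function(table, hi = 3, lo = 1) {
  stopifnot(inherits(table, "expression_table"))
  if (hi < lo) stop("hi threshold must be >= lo threshold")
  gm <- table$group_means
  if (ncol(gm) < 2L) stop("call_specific needs at least 2 groups")
  specific <- rep(NA_character_, nrow(gm))
  for (j in seq_len(ncol(gm))) {
    others <- gm[, -j, drop = FALSE]
    ok <- gm[, j] > hi & apply(others < lo, 1L, all)
    specific[ok] <- colnames(gm)[j]
  }
  data.frame(transcript_id = rownames(gm), specific_in = specific,
             stringsAsFactors = FALSE)
}

#' Most abundant transcripts of a group
#'
#' @param table an expression_table.
#' @param group group label.
#' @param n number of ids to return (default 1000; truncated to the set
#'   size). Ties break lexicographically.
#' @return character vector of transcript ids, descending group-mean FPKM.
#' @export
top_abundant <- function(table, group, n = 1000L) {
  stopifnot(inherits(table, "expression_table"), n >= 1L)
  if (!group %in% colnames(table$group_means)) {
    stop("unknown group: ", group)
  }
  v <- table$group_means[, group]
  ids <- rownames(table$group_means)
  ord <- order(-v, ids, method = "radix")
  ids[ord][seq_len(min(n, length(ids)))]
}

#' Co-expression of candidate transcripts with seed transcripts
#'
#' Pearson correlation of `log2(FPKM + 1)` across all samples, for every
#' (seed, candidate) pair of distinct transcripts. Transcripts with zero
#' variance across samples are skipped with a warning.
#'
#' @param table an expression_table with >= 3 samples.
#' @param seed_ids,candidate_ids transcript id vectors (must exist).
#' @param min_abs_r report pairs with `|r| >= min_abs_r` (default 0.9).
#' @return data.frame `seed`, `candidate`, `r`, sorted by `|r|` descending.
#' @export
coexpression <- function(table, seed_ids, candidate_ids, min_abs_r = 0.9) {
  stopifnot(inherits(table, "expression_table"))
  if (ncol(table$fpkm) < 3L) stop("coexpression needs at least 3 samples")
  ids <- unique(c(seed_ids, candidate_ids))
  unknown <- setdiff(ids, rownames(table$fpkm))
  if (length(unknown)) {
    stop("unknown transcript id(s): ", paste(unknown, collapse = ", "))
  }
  lx <- log2(table$fpkm[ids, , drop = FALSE] + 1)
  sds <- apply(lx, 1L, stats::sd)
  flat <- ids[sds == 0]
  if (length(flat)) {
    warning("skipping zero-variance transcript(s): ",
            paste(utils::head(flat, 5L), collapse = ", "))
  }
  seeds <- setdiff(seed_ids, flat)
  cands <- setdiff(candidate_ids, flat)
  pairs <- expand.grid(seed = seeds, candidate = cands,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$seed != pairs$candidate, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    return(data.frame(seed = character(0), candidate = character(0),
                      r = numeric(0), stringsAsFactors = FALSE))
  }
  cm <- stats::cor(t(lx[seeds, , drop = FALSE]) ,
                   t(lx[cands, , drop = FALSE]))
  pairs$r <- cm[cbind(match(pairs$seed, seeds),
                      match(pairs$candidate, cands))]
  pairs <- pairs[abs(pairs$r) >= min_abs_r, , drop = FALSE]
  pairs <- pairs[order(-abs(pairs$r), pairs$seed, pairs$candidate,
                       method = "radix"), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Write an FPKM matrix as TSV
#' @param table an expression_table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fpkm_tsv <- function(table, path) {
  stopifnot(inherits(table, "expression_table"))
  df <- data.frame(transcript_id = rownames(table$fpkm), table$fpkm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
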