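#' Exact negative-binomial conditional test for a two-group comparison
#'
#' Tests equality of means between two groups of library-size-equalized
#' counts under a negative-binomial model with a common dispersion
#' `phi` (variance `mu + phi * mu^2`). Conditioning on the pooled total
#' `t`, the group-A sum follows a negative hypergeometric distribution
#' with shape parameters `n_a / phi` and `n_b / phi` (independent of the
#' NB probability parameter); at `phi = 0` this reduces to the
#' conditional binomial of the Poisson model. The two-sided p-value sums
#' the probabilities of all outcomes no more likely than the observed one.
#'
#' @param counts_a,counts_b numeric vectors of equalized counts (>= 1
#'   replicate each; rounded to integers internally).
#' @param dispersion common NB dispersion `phi >= 0`.
#' @return p-value in (0, 1]; 1 when both groups are all zero.
#' @export
exact_nb_test <- function(counts_a, counts_b, dispersion = 0) {
  stopifnot(length(counts_a) >= 1L, length(counts_b) >= 1L,
            dispersion >= 0)
  sa <- round(sum(counts_a))
  sb <- round(sum(counts_b))
  t <- sa + sb
  if (t == 0) return(1)
  na <- length(counts_a)
  nb <- length(counts_b)
  s <- 0:t
  if (dispersion == 0) {
    logp <- stats::dbinom(s, t, na / (na + nb), log = TRUE)
  } else {
    r1 <- na / dispersion
    r2 <- nb / dispersion
    logp <- lchoose(s + r1 - 1, s) + lchoose(t - s + r2 - 1, t - s) -
      lchoose(t + r1 + r2 - 1, t)
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  min(1, sum(p[p <= p[sa + 1] * (1 + 1e-7)]))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, capped at 1.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Method-of-moments common dispersion estimate
#'
#' Per transcript and group, the moment estimate is
#' `(var - mean) / mean^2` on equalized counts; the common dispersion is
#' the median of the positive per-transcript averages (0 when all are at
#' or below the Poisson limit). Groups need >= 2 replicates to contribute.
#'
#' @param m equalized count matrix (transcripts x samples).
#' @param groups named character vector sample -> group.
#' @return a single dispersion estimate `>= 0`.
#' @export
estimate_common_dispersion <- function(m, groups) {
  glev <- unique(groups)
  ests <- matrix(NA_real_, nrow(m), length(glev))
  for (j in seq_along(glev)) {
    cols <- which(groups == glev[j])
    if (length(cols) < 2L) next
    mu <- rowMeans(m[, cols, drop = FALSE])
    v <- apply(m[, cols, drop = FALSE], 1L, stats::var)
    ok <- mu > 0
    ests[ok, j] <- (v[ok] - mu[ok]) / mu[ok]^2
  }
  per_t <- rowMeans(ests, na.rm = TRUE)
  per_t <- per_t[is.finite(per_t)]
  if (!length(per_t)) return(0)
  max(0, stats::median(per_t))
}

# Scale every sample's counts to the geometric-mean library size and round
# to the nearest integer (conditional exact tests need integer counts).
equalize_library_sizes <- function(m) {
  libsize <- colSums(m)
  if (any(libsize <= 0)) stop("zero library size")
  target <- exp(mean(log(libsize)))
  round(sweep(m, 2L, target / libsize, "*"))
}

#' Call differentially expressed transcripts between two groups
#'
#' Counts of the two groups' samples are equalized to a common library
#' size, tested per transcript with [exact_nb_test()] under a common
#' dispersion, and adjusted with [bh_adjust()]. The log2 fold change uses
#' group means of equalized counts with a pseudo-count. A transcript is
#' differentially expressed when `fdr <= fdr_max` and the fold change is
#' at least `fc_min` (i.e. `|log2FC| >= log2(fc_min)`), both inclusive.
#'
#' @param table an [compute_fpkm()] expression_table.
#' @param group_a,group_b group labels to contrast.
#' @param dispersion common dispersion; `NULL` (default) estimates it by
#'   [estimate_common_dispersion()] on the two groups.
#' @param fc_min fold-change threshold (default 2).
#' @param fdr_max FDR threshold (default 0.01).
#' @param pseudo_count fragments added to each group mean for the fold
#'   change (default 1).
#' @return data.frame: `transcript_id`, `group_a`, `group_b`,
#'   `log2_fold_change`, `p_value`, `fdr`, `is_de`.
#' @export
call_de <- function(table, group_a, group_b, dispersion = NULL,
                    fc_min = 2, fdr_max = 0.01, pseudo_count = 1) {
  stopifnot(inherits(table, "expression_table"))
  groups <- table$groups
  for (g in c(group_a, group_b)) {
    if (!g %in% groups) stop("unknown group: ", g)
  }
  cols <- groups %in% c(group_a, group_b)
  m <- equalize_library_sizes(table$counts$counts[, cols, drop = FALSE])
  sub_groups <- groups[cols]
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(m, sub_groups)
  }
  a_cols <- sub_groups == group_a
  b_cols <- sub_groups == group_b
  p <- vapply(seq_len(nrow(m)), function(i) {
    exact_nb_test(m[i, a_cols], m[i, b_cols], dispersion)
  }, 0)
  fdr <- bh_adjust(p)
  mean_a <- rowMeans(m[, a_cols, drop = FALSE])
  mean_b <- rowMeans(m[, b_cols, drop = FALSE])
  lfc <- log2((mean_a + pseudo_count) / (mean_b + pseudo_count))
  data.frame(transcript_id = rownames(m), group_a = group_a,
             group_b = group_b, log2_fold_change = lfc, p_value = p,
             fdr = fdr,
             is_de = fdr <= fdr_max & abs(lfc) >= log2(fc_min),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential expression over all pairwise group contrasts
#'
#' Runs [call_de()] for every unordered group pair and returns the pooled
#' result; `de_union` lists transcripts called in at least one contrast
#' (the pooled-union reading of "differential among samples").
#'
#' @inheritParams call_de
#' @return list with `contrasts` (row-bound [call_de()] tables) and
#'   `de_union` (character vector of transcript ids).
#' @export
call_de_all_pairs <- function(table, dispersion = NULL, fc_min = 2,
                              fdr_max = 0.01, pseudo_count = 1) {
  glev <- unique(table$groups)
  if (length(glev) < 2L) stop("need at least 2 groups")
  out <- list()
  for (i in seq_along(glev)) {
    for (j in seq_along(glev)) {
      if (j <= i) next
      out[[length(out) + 1L]] <-
        call_de(table, glev[i], glev[j], dispersion, fc_min, fdr_max,
                pseudo_count)
    }
  }
  contrasts <- do.call(rbind, out)
  list(contrasts = contrasts,
       de_union = sort(unique(contrasts$transcript_id[contrasts$is_de])))
}
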