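# Independent oracles used by the property and acceptance tests. Each one
# deliberately takes a different computational route from the package
# implementation it checks.

# --- brute-force single-linkage clustering over intervals --------------------

# Pairwise union-find over all interval pairs: intervals i, j are linked iff
# min(end) - max(start) >= min_overlap. Returns component labels.
oracle_interval_components <- function(starts, ends, min_overlap = 1) {
  n <- length(starts)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (min(ends[i], ends[j]) - max(starts[i], starts[j]) >= min_overlap) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, 0L)
}

# Canonical partition signature (set of sorted member index sets).
partition_signature <- function(labels, ids = seq_along(labels)) {
  groups <- split(ids, labels)
  sig <- sort(vapply(groups, function(g)
    paste(sort(as.character(g)), collapse = ","), character(1)))
  unname(sig)
}

# --- N50 / assembly stats ----------------------------------------------------

oracle_n50 <- function(lengths) {
  sorted <- sort(lengths, decreasing = TRUE)
  total <- sum(as.numeric(sorted))
  acc <- 0
  for (L in sorted) {
    acc <- acc + L
    if (acc >= total / 2) return(L)
  }
}

# --- exhaustive six-frame ORF enumeration ------------------------------------

# Translates each frame with Biostrings::translate (fuzzy codons -> X) and
# enumerates every candidate (edge- or M-started run up to a stop or the
# edge) by string parsing; returns the best per the package's declared
# tie-break or NULL.
oracle_best_orf <- function(sequence, min_orf_aa = 100L) {
  s <- toupper(sequence)
  L <- nchar(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  frames <- list(c("+1", 0, 0), c("+2", 1, 0), c("+3", 2, 0),
                 c("-1", 0, 1), c("-2", 1, 1), c("-3", 2, 1))
  best <- NULL
  cands <- list()
  for (rank in seq_along(frames)) {
    fr <- frames[[rank]]
    off <- as.integer(fr[2])
    seqstr <- if (fr[3] == "1") rc else s
    n_cod <- (nchar(seqstr) - off) %/% 3
    if (n_cod < 1) next
    dna <- Biostrings::DNAString(substr(seqstr, off + 1, off + 3 * n_cod))
    pep <- as.character(Biostrings::translate(dna, if.fuzzy.codon = "X"))
    # segments between stops
    stop_pos <- which(strsplit(pep, "")[[1]] == "*")
    seg_start <- c(1L, stop_pos + 1L)
    seg_end <- c(stop_pos - 1L, nchar(pep))
    for (k in seq_along(seg_start)) {
      a <- seg_start[k]; b <- seg_end[k]
      if (b < a) next
      terminated <- k <= length(stop_pos)
      seg <- substr(pep, a, b)
      starts <- integer(0)
      if (a == 1L) starts <- 1L
      m <- regexpr("M", seg, fixed = TRUE)
      if (m > 0 && !(a == 1L && m == 1L)) starts <- c(starts, a + m - 1L)
      for (st in starts) {
        aa <- b - st + 1L
        if (aa < min_orf_aa) next
        has_start <- substr(pep, st, st) == "M"
        nt_start_f <- off + 3 * (st - 1)
        nt_end_f <- off + 3 * b + if (terminated) 3 else 0
        if (fr[3] == "1") {
          start <- L - nt_end_f; end <- L - nt_start_f
        } else {
          start <- nt_start_f; end <- nt_end_f
        }
        cand <- list(frame = fr[1], rank = rank, start_codon = st, aa = aa,
                     has_start = has_start, has_stop = terminated,
                     start = start, end = end)
        cands[[length(cands) + 1]] <- cand
        if (is.null(best) || cand$aa > best$aa ||
            (cand$aa == best$aa &&
             (cand$rank < best$rank ||
              (cand$rank == best$rank &&
               cand$start_codon < best$start_codon)))) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$category <- if (best$has_start && best$has_stop) "complete"
  else if (best$has_stop) "five_prime_partial"
  else if (best$has_start) "three_prime_partial"
  else "internal"
  best$unique_max <- sum(vapply(cands, function(x) x$aa, 0) == best$aa) == 1
  best
}

random_dna_string <- function(len, with_n = FALSE) {
  alpha <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  prob <- if (with_n) c(rep(0.2425, 4), 0.03) else NULL
  paste(sample(alpha, len, replace = TRUE, prob = prob), collapse = "")
}

# --- literal Benjamini-Hochberg step-up --------------------------------------

oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    adj[ord[i]] <- running
  }
  adj
}

# --- PROSITE scanning via exhaustive regex expansion -------------------------

AA20_TEST <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Random constrained pattern: 2-5 elements, at most 2 variable repeats.
random_prosite_pattern <- function() {
  n <- sample(2:5, 1)
  n_var <- 0
  toks <- character(n)
  for (i in seq_len(n)) {
    kind <- sample(c("literal", "class", "negated", "wildcard"), 1,
                   prob = c(0.35, 0.2, 0.15, 0.3))
    base <- switch(kind,
      literal = sample(AA20_TEST, 1),
      class = paste0("[", paste(sort(sample(AA20_TEST, sample(2:4, 1))),
                                collapse = ""), "]"),
      negated = paste0("{", paste(sort(sample(AA20_TEST, sample(2:10, 1))),
                                  collapse = ""), "}"),
      wildcard = "x")
    rep_suffix <- ""
    if (stats::runif(1) < 0.35) {
      if (n_var < 2 && stats::runif(1) < 0.5) {
        a <- sample(1:2, 1)
        rep_suffix <- sprintf("(%d,%d)", a, a + sample(1:2, 1))
        n_var <- n_var + 1
      } else {
        rep_suffix <- sprintf("(%d)", sample(1:3, 1))
      }
    }
    toks[i] <- paste0(base, rep_suffix)
  }
  paste0(if (stats::runif(1) < 0.15) "<" else "",
         paste(toks, collapse = "-"),
         if (stats::runif(1) < 0.15) ">" else "")
}

# Expand a parsed pattern into all fixed-length regexes over the peptide
# alphabet (20 aa + X), then report the shortest match at each start.
oracle_scan <- function(pattern_string, peptide) {
  p <- nrunigene::parse_prosite(pattern_string)
  chunk <- function(el) {
    switch(el$kind,
      wildcard = "[ACDEFGHIKLMNPQRSTVWYX]",
      literal = el$residues,
      class = paste0("[", paste(el$residues, collapse = ""), "]"),
      negated = paste0("[^", paste(c(el$residues, "X", "*"), collapse = ""),
                       "]"))
  }
  counts <- lapply(p$elements, function(el) el$min:el$max)
  grid <- expand.grid(counts)
  regexes <- apply(grid, 1, function(cnt) {
    paste0(mapply(function(el, k) {
      paste(rep(chunk(el), k), collapse = "")
    }, p$elements, cnt), collapse = "")
  })
  lens <- rowSums(grid)
  n <- nchar(peptide)
  starts <- if (p$n_anchor) 1 else seq_len(n)
  hits <- NULL
  for (s in starts) {
    match_lens <- numeric(0)
    for (r in seq_along(regexes)) {
      tail_str <- substr(peptide, s, n)
      re <- paste0("^", regexes[r], if (p$c_anchor) "$" else "")
      if (grepl(re, tail_str)) match_lens <- c(match_lens, lens[r])
    }
    if (length(match_lens)) {
      hits <- rbind(hits, data.frame(start = s - 1,
                                     end = s - 1 + min(match_lens)))
    }
  }
  if (is.null(hits)) data.frame(start = integer(0), end = integer(0))
  else hits
}

random_peptide <- function(len, pattern_string = NULL) {
  chars <- sample(c(AA20_TEST, "X"), len, replace = TRUE,
                  prob = c(rep(0.0475, 20), 0.05))
  pep <- paste(chars, collapse = "")
  pep
}

# --- per-base interval coverage ----------------------------------------------

oracle_covered_length <- function(starts, ends, len) {
  covered <- logical(len)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) covered[(starts[i] + 1):ends[i]] <- TRUE
  }
  sum(covered)
}
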