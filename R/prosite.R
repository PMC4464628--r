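AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Parse a PROSITE-syntax pattern
#'
#' Supported syntax: elements separated by `-`; a single residue letter, a
#' residue class `[...]`, a negated class `{...}`, or the wildcard `x`;
#' an optional repeat `(n)` or `(n,m)` attached to the preceding element
#' (`n >= 1`, `m >= n`); a leading `<` anchors the match to the peptide
#' N terminus and a trailing `>` to the C terminus; an optional trailing
#' `.` terminator.
#'
#' @param pattern pattern string.
#' @return A `prosite_pattern`: list with `raw`, `n_anchor`, `c_anchor`
#'   and `elements` (each `list(kind, residues, min, max)` with kind one
#'   of `"literal"`, `"class"`, `"negated"`, `"wildcard"`).
#' @export
parse_prosite <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  raw <- pattern
  p <- sub("\\.$", "", trimws(pattern))
  n_anchor <- startsWith(p, "<")
  if (n_anchor) p <- substring(p, 2L)
  c_anchor <- endsWith(p, ">")
  if (c_anchor) p <- substring(p, 1L, nchar(p) - 1L)
  if (!nzchar(p)) stop("empty pattern body")
  toks <- strsplit(p, "-", fixed = TRUE)[[1L]]
  elements <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    tok <- toks[i]
    if (!nzchar(tok)) stop("empty element at position ", i)
    rep_min <- 1L
    rep_max <- 1L
    rep_m <- regexec("^(.*)\\(([0-9]+)(,([0-9]+))?\\)$", tok)[[1L]]
    if (rep_m[1L] != -1L) {
      parts <- regmatches(tok, list(rep_m))[[1L]]
      tok <- parts[2L]
      if (!nzchar(tok)) stop("repeat with no preceding element at position ", i)
      rep_min <- as.integer(parts[3L])
      rep_max <- if (nzchar(parts[5L])) as.integer(parts[5L]) else rep_min
      if (rep_min < 1L || rep_max < rep_min) {
        stop("invalid repeat bounds (", rep_min, ",", rep_max,
             ") at position ", i)
      }
    }
    if (tok == "x") {
      el <- list(kind = "wildcard", residues = character(0))
    } else if (grepl("^\\[[A-Z]+\\]$", tok)) {
      el <- list(kind = "class",
                 residues = strsplit(substring(tok, 2L, nchar(tok) - 1L),
                                     "")[[1L]])
    } else if (grepl("^\\{[A-Z]+\\}$", tok)) {
      el <- list(kind = "negated",
                 residues = strsplit(substring(tok, 2L, nchar(tok) - 1L),
                                     "")[[1L]])
    } else if (grepl("^[A-Z]$", tok)) {
      el <- list(kind = "literal", residues = tok)
    } else {
      stop("unrecognised pattern element '", tok, "' at position ", i)
    }
    if (length(el$residues) && !all(el$residues %in% AA20)) {
      stop("non-amino-acid residue in element '", toks[i],
           "' at position ", i)
    }
    el$min <- rep_min
    el$max <- rep_max
    elements[[i]] <- el
  }
  structure(list(raw = raw, n_anchor = n_anchor, c_anchor = c_anchor,
                 elements = elements),
            class = "prosite_pattern")
}

#' Render a parsed PROSITE pattern back to its string form
#'
#' `parse_prosite(render_prosite(parse_prosite(p)))` is stable.
#'
#' @param pattern a `prosite_pattern`.
#' @return the pattern string (canonical form, no trailing dot).
#' @export
render_prosite <- function(pattern) {
  stopifnot(inherits(pattern, "prosite_pattern"))
  body <- vapply(pattern$elements, function(el) {
    base <- switch(el$kind,
                   wildcard = "x",
                   literal = el$residues,
                   class = paste0("[", paste(el$residues, collapse = ""), "]"),
                   negated = paste0("{", paste(el$residues, collapse = ""), "}"))
    if (el$min == 1L && el$max == 1L) base
    else if (el$min == el$max) sprintf("%s(%d)", base, el$min)
    else sprintf("%s(%d,%d)", base, el$min, el$max)
  }, character(1))
  paste0(if (pattern$n_anchor) "<" else "", paste(body, collapse = "-"),
         if (pattern$c_anchor) ">" else "")
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat("<prosite_pattern> ", render_prosite(x), "\n", sep = "")
  invisible(x)
}

# Does residue ch satisfy element el? X matches only wildcards; * (stop)
# matches nothing.
element_matches <- function(el, ch) {
  if (ch == "*") return(FALSE)
  switch(el$kind,
         wildcard = ch %in% c(AA20, "X"),
         literal = ch == el$residues,
         class = ch %in% el$residues,
         negated = ch != "X" && !(ch %in% el$residues))
}

#' Scan a peptide with a PROSITE pattern
#'
#' Reports, for every start position admitting a match, the shortest match
#' at that position (variable repeats expand minimally). Overlapping
#' matches from different start positions are all reported. Peptides may
#' contain `X` (matches only wildcard positions) and `*` (matches
#' nothing).
#'
#' @param pattern a `prosite_pattern` or pattern string.
#' @param peptide amino-acid string.
#' @return data.frame of hits: `start`, `end` (0-based half-open on the
#'   peptide) and `match` (the matched subsequence).
#' @export
scan_protein <- function(pattern, peptide) {
  if (is.character(pattern)) pattern <- parse_prosite(pattern)
  stopifnot(inherits(pattern, "prosite_pattern"))
  chars <- strsplit(toupper(peptide), "")[[1L]]
  n <- length(chars)
  els <- pattern$elements
  starts <- if (pattern$n_anchor) 1L else seq_len(max(n, 0L))
  hits <- list()
  for (s in starts) {
    # Forward DP over elements: the set of positions reachable after each
    # element; the minimal final position is the shortest match.
    reach <- s
    for (el in els) {
      nxt <- integer(0)
      for (pos in reach) {
        p <- pos
        k <- 0L
        while (k < el$max && p <= n && element_matches(el, chars[p])) {
          k <- k + 1L
          p <- p + 1L
          if (k >= el$min) nxt <- c(nxt, p)
        }
      }
      reach <- unique(nxt)
      if (!length(reach)) break
    }
    if (!length(reach)) next
    if (pattern$c_anchor) reach <- reach[reach == n + 1L]
    if (!length(reach)) next
    e <- min(reach)
    hits[[length(hits) + 1L]] <-
      data.frame(start = s - 1L, end = e - 1L,
                 match = paste(chars[s:(e - 1L)], collapse = ""),
                 stringsAsFactors = FALSE)
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      match = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}
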