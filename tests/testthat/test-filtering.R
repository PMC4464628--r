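make_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(query_id = r[[1]], subject_id = "db",
               identity_pct = as.numeric(r[[2]]),
               align_len = as.integer(r[[3]]),
               evalue = as.numeric(r[[4]]), bitscore = 100,
               stringsAsFactors = FALSE)
  }))
}

test_that("filter_contaminants removes only hits passing all thresholds", {
  ts <- transcript_set(c("t1", "t2", "t3"),
                       vapply(c(1000, 1000, 400),
                              function(n) strrep("ACGT", n / 4),
                              character(1)))
  hits <- make_hits(list("t1", 98, 900, 1e-80),   # all thresholds met
                    list("t2", 98, 900, 1))       # evalue fails
  res <- filter_contaminants(ts, hits, 1e-10, 90, 0.5)
  expect_equal(res$removed_ids, "t1")
  expect_equal(res$kept$id, c("t2", "t3"))
  # no hits at all -> everything kept
  res0 <- filter_contaminants(ts, hits[0, ], 1e-10, 90, 0.5)
  expect_equal(nrow(res0$kept), 3L)
  # unknown id -> warning, hit ignored
  expect_warning(
    resw <- filter_contaminants(ts, make_hits(list("zz", 99, 900, 1e-80))),
    "unknown")
  expect_equal(length(resw$removed_ids), 0L)
})

test_that("filter_rrna uses the interval union of predictions", {
  ts <- transcript_set(c("a", "b", "c"), rep(strrep("A", 1000), 3))
  preds <- data.frame(
    transcript_id = c("a", "b", "c", "c"),
    start = c(0L, 0L, 0L, 400L),
    end = c(900L, 100L, 600L, 900L), score = 50)
  res <- filter_rrna(ts, preds, 0.5)
  # a: 0.9 removed; b: 0.1 kept; c: union(0,600)+(400,900) = 900 removed
  expect_setequal(res$removed_ids, c("a", "c"))
  bad <- data.frame(transcript_id = "a", start = 0L, end = 2000L, score = 1)
  expect_error(filter_rrna(ts, bad, 0.5), "out of transcript bounds")
})

test_that("rRNA covered length equals a per-base marking oracle", {
  set.seed(31)
  len <- 500L
  ts <- transcript_set("t", strrep("A", len))
  for (rep_i in 1:100) {
    k <- sample(1:6, 1)
    starts <- sample(0:(len - 10L), k)
    ends <- pmin(len, starts + sample(5:200, k, TRUE))
    preds <- data.frame(transcript_id = "t", start = starts, end = ends,
                        score = 1)
    covered <- oracle_covered_length(starts, ends, len)
    res <- filter_rrna(ts, preds, min_rrna_fraction = covered / len)
    expect_equal(res$removed_ids, "t")   # exactly at threshold
    if (covered < len) {
      res2 <- filter_rrna(ts, preds,
                          min_rrna_fraction = (covered + 1) / len)
      expect_equal(length(res2$removed_ids), 0L)
    }
  }
})

test_that("flag_noncoding requires absence of both ORF and homology", {
  ts <- transcript_set(c("orf", "hom", "lnc"),
                       rep(strrep("ACGT", 100), 3))
  orfs <- data.frame(transcript_id = "orf", aa_length = 150L)
  hits <- make_hits(list("hom", 80, 100, 1e-20))
  flagged <- flag_noncoding(ts, orfs, hits, min_orf_aa = 100,
                            max_evalue = 1e-5)
  expect_equal(flagged, "lnc")
  # homology above the threshold does not rescue
  weak <- make_hits(list("hom", 80, 100, 1e-3))
  expect_setequal(flag_noncoding(ts, orfs, weak), c("hom", "lnc"))
})

test_that("filter cascade attributes removals to the first stage", {
  set.seed(61)
  # 10 transcripts; t1 t2 contaminant; t3 rRNA; one true lncRNA decoy.
  seqs <- c(replicate(9, nrunigene:::planted_transcript(
    "complete", sample(110:150, 1), 90L, 300L)),
    local({
      for (i in 1:50) {
        s <- nrunigene:::stopweave(450L)
        if (is.null(find_best_orf(list(id = "x", sequence = s), 100L)))
          return(s)
      }
      stop("no lnc decoy")
    }))
  ts <- transcript_set(sprintf("t%d", 1:10), seqs)
  contam <- make_hits(list("t1", 99, 900, 1e-80),
                      list("t2", 99, 900, 1e-80),
                      list("t3", 99, 900, 1e-80))  # t3 also matches rRNA
  preds <- data.frame(transcript_id = "t3", start = 0L,
                      end = as.integer(0.9 * ts$length[3]), score = 60)
  prot <- do.call(rbind, lapply(sprintf("t%d", 1:9), function(id)
    make_hits(list(id, 90, 300, 1e-30))))
  res <- run_filter_cascade(ts, contam, preds, prot)
  r <- res$report
  expect_equal(r$initial_count, 10L)
  expect_equal(r$removed_contaminant, 3L)  # t3 counted here, not under rRNA
  expect_equal(r$removed_rrna, 0L)
  expect_equal(r$removed_lncrna, 1L)
  expect_equal(r$final_count, 6L)
  expect_equal(r$removed_fraction, 0.4)
  expect_true(all(res$kept$id %in% ts$id))
})

test_that("cascade with empty evidence removes only ORF-free transcripts", {
  set.seed(62)
  seqs <- replicate(5, nrunigene:::planted_transcript(
    "complete", 120L, 90L, 240L))
  ts <- transcript_set(sprintf("g%d", 1:5), seqs)
  res <- run_filter_cascade(ts)
  expect_equal(res$report$removed_contaminant, 0L)
  expect_equal(res$report$removed_rrna, 0L)
  expect_equal(res$report$removed_lncrna, 0L)
  expect_equal(res$report$final_count, 5L)
  expect_equal(res$report$removed_fraction, 0)
})
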