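single_exon_alignments <- function(starts, ends, ids = NULL,
                                   scaffold = "sc1", strand = "+",
                                   identity = NULL) {
  n <- length(starts)
  if (is.null(ids)) ids <- sprintf("t%03d", seq_len(n))
  if (is.null(identity)) identity <- rep(99, n)
  alignment_set(ids, rep(scaffold, n), rep(strand, n),
                lapply(seq_len(n), function(i) rbind(c(starts[i], ends[i]))),
                identity, rep(99, n))
}

test_that("cluster_by_locus links overlapping spans into loci", {
  aln <- single_exon_alignments(c(0, 50), c(100, 150))
  cl <- cluster_by_locus(aln)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, 0)
  expect_equal(cl$end, 150)
  expect_setequal(cl$member_ids[[1]], c("t001", "t002"))

  cl2 <- cluster_by_locus(single_exon_alignments(c(0, 200), c(100, 300)))
  expect_equal(nrow(cl2), 2L)
  expect_equal(nrow(cluster_by_locus(single_exon_alignments(numeric(0),
                                                            numeric(0)))),
               0L)
})

test_that("strand awareness separates antisense overlaps", {
  aln <- alignment_set(c("p", "m"), c("sc1", "sc1"), c("+", "-"),
                       list(rbind(c(0, 100)), rbind(c(10, 90))),
                       c(99, 99), c(99, 99))
  expect_equal(nrow(cluster_by_locus(aln, strand_aware = TRUE)), 2L)
  merged <- cluster_by_locus(aln, strand_aware = FALSE)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$strand, "merged")
})

test_that("multi-placement transcripts go to their best placement's cluster", {
  # tX has a 99%-identity placement overlapping tA and a 96% one
  # overlapping tB; it must join tA's cluster only.
  aln <- alignment_set(
    c("tA", "tX", "tX", "tB"), rep("sc1", 4), rep("+", 4),
    list(rbind(c(0, 100)), rbind(c(50, 150)), rbind(c(1000, 1100)),
         rbind(c(1050, 1200))),
    c(99, 99, 96, 99), rep(99, 4))
  cl <- cluster_by_locus(aln)
  expect_equal(nrow(cl), 2L)
  expect_setequal(cl$member_ids[[1]], c("tA", "tX"))
  expect_setequal(cl$member_ids[[2]], "tB")
})

test_that("clustering matches the pairwise union-find oracle", {
  set.seed(71)
  for (rep_i in 1:60) {
    n <- sample(5:60, 1)
    min_ov <- sample(c(1L, 5L, 25L), 1)
    starts <- sample(0:3000, n, replace = TRUE)
    ends <- starts + sample(10:400, n, replace = TRUE)
    ids <- sprintf("t%03d", seq_len(n))
    aln <- single_exon_alignments(starts, ends, ids)
    cl <- cluster_by_locus(aln, min_overlap_bp = min_ov)
    got <- partition_signature(rep(seq_len(nrow(cl)), lengths(cl$member_ids)),
                               unlist(cl$member_ids))
    lab <- oracle_interval_components(starts, ends, min_ov)
    expect_equal(got, partition_signature(lab, ids))
    # footprint equals the union-span of member spans
    for (k in seq_len(nrow(cl))) {
      m <- match(cl$member_ids[[k]], ids)
      expect_equal(cl$start[k], min(starts[m]))
      expect_equal(cl$end[k], max(ends[m]))
    }
  }
})

test_that("select_representative prefers length then lexicographic id", {
  ts <- transcript_set(c("t1", "t2", "a", "b", "solo"),
                       c(strrep("A", 500), strrep("A", 900),
                         strrep("A", 700), strrep("A", 700),
                         strrep("A", 10)))
  expect_equal(select_representative(c("t1", "t2"), ts), "t2")
  expect_equal(select_representative(c("a", "b"), ts), "a")
  expect_equal(select_representative("solo", ts), "solo")
  expect_error(select_representative(c("t1", "zz"), ts), "unknown member")
})

test_that("collapse_unaligned keeps the longest isoform per component", {
  ts <- transcript_set(c("X_c0_seq1", "X_c0_seq2", "Y_c1_seq1", "plain"),
                       c(strrep("A", 300), strrep("A", 450),
                         strrep("A", 200), strrep("A", 50)))
  expect_equal(collapse_unaligned(ts),
               sort(c("X_c0_seq2", "Y_c1_seq1", "plain")))
  expect_equal(collapse_unaligned(ts[0, ]), character(0))
})

test_that("assembly_stats matches examples and rejects empty input", {
  s <- assembly_stats(c(5, 4, 3, 2, 1))
  expect_equal(s$n50, 4L)          # cumulative 5, 9 >= 7.5
  expect_equal(s$mean_len, 3L)
  s1 <- assembly_stats(10)
  expect_equal(unlist(s1[c("count", "max_len", "mean_len", "n50")]),
               c(count = 1L, max_len = 10L, mean_len = 10L, n50 = 10L))
  expect_equal(assembly_stats(c(2, 2, 2, 2))$n50, 2L)
  expect_error(assembly_stats(integer(0)), "empty")
})

test_that("build_unigene_set recovers planted loci and components", {
  # 5 loci x 3 isoforms aligned + 2 unaligned components x 2 isoforms
  ids <- character(0)
  seqs <- character(0)
  starts <- numeric(0)
  ends <- numeric(0)
  aln_ids <- character(0)
  for (k in 1:5) {
    base <- 2000 * k
    for (j in 1:3) {
      id <- sprintf("L%d_c0_seq%d", k, j)
      len <- 300 + 100 * j
      ids <- c(ids, id)
      seqs <- c(seqs, strrep("A", len))
      aln_ids <- c(aln_ids, id)
      starts <- c(starts, base)
      ends <- c(ends, base + len)
    }
  }
  for (u in 1:2) {
    for (j in 1:2) {
      id <- sprintf("U%d_c0_seq%d", u, j)
      ids <- c(ids, id)
      seqs <- c(seqs, strrep("A", 150 + 50 * j))
    }
  }
  ts <- transcript_set(ids, seqs)
  aln <- single_exon_alignments(starts, ends, aln_ids)
  nr <- build_unigene_set(ts, aln)
  expect_equal(nr$stats$count, 7L)
  expect_equal(nr$n_loci, 5L)
  expect_equal(nr$n_unaligned_components, 2L)
  expect_setequal(nr$representatives$id,
                  c(sprintf("L%d_c0_seq3", 1:5), sprintf("U%d_c0_seq2", 1:2)))
  # every input transcript maps to exactly one representative
  expect_equal(sort(names(nr$representative_of)), sort(ids))
  expect_true(all(nr$representative_of %in% nr$representatives$id))
  # degenerate: nothing aligned -> same as collapse_unaligned
  nr0 <- build_unigene_set(ts, aln[0, ])
  expect_setequal(nr0$representatives$id, collapse_unaligned(ts))
  # single transcript
  one <- transcript_set("only_c0_seq1", strrep("A", 400))
  expect_equal(build_unigene_set(one, aln[0, ])$stats$count, 1L)
})
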