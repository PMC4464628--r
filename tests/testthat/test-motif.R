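test_that("parse_prosite builds the declared AST and rejects bad input", {
  p <- parse_prosite("A-x(2)-G")
  expect_equal(vapply(p$elements, `[[`, "", "kind"),
               c("literal", "wildcard", "literal"))
  expect_equal(p$elements[[2]]$min, 2L)
  expect_equal(p$elements[[2]]$max, 2L)

  q <- parse_prosite("[FW]-x(2,3)-G.")
  expect_equal(q$elements[[1]]$residues, c("F", "W"))
  expect_equal(q$elements[[2]]$min, 2L)
  expect_equal(q$elements[[2]]$max, 3L)

  a <- parse_prosite("<M-{P}-A>")
  expect_true(a$n_anchor && a$c_anchor)
  expect_equal(a$elements[[2]]$kind, "negated")

  expect_error(parse_prosite("A-x(3,2)"), "repeat bounds")
  expect_error(parse_prosite("A-[FG"), "unrecognised")
  expect_error(parse_prosite("A--G"), "empty element")
  expect_error(parse_prosite("A-j"), "unrecognised")
})

test_that("parse -> render -> parse is stable", {
  set.seed(91)
  for (i in 1:60) {
    pat <- random_prosite_pattern()
    p1 <- parse_prosite(pat)
    r1 <- render_prosite(p1)
    p2 <- parse_prosite(r1)
    expect_equal(render_prosite(p2), r1)
    expect_equal(p2$elements, p1$elements)
  }
})

test_that("scan_protein matches spec examples", {
  hits <- scan_protein("A-x(2)-G", "ZZAXXGZZ")
  expect_equal(nrow(hits), 1L)
  expect_equal(c(hits$start, hits$end), c(2L, 6L))

  expect_equal(nrow(scan_protein("<M-A", "MAZ")), 1L)
  expect_equal(scan_protein("<M-A", "MAZ")$start, 0L)
  expect_equal(nrow(scan_protein("<M-A", "ZMA")), 0L)
  expect_equal(scan_protein("M-A>", "ZMA")$start, 1L)

  # shortest match per start for variable repeats
  v <- scan_protein("A-x(1,3)-G", "AKGKG")
  expect_equal(v$end[v$start == 0], 3L)
  # X matches only wildcards
  expect_equal(nrow(scan_protein("[AC]-G", "XG")), 0L)
  expect_equal(nrow(scan_protein("{P}-G", "XG")), 0L)
  expect_equal(nrow(scan_protein("x-G", "XG")), 1L)
})

test_that("scan_protein agrees with the regex-expansion oracle", {
  set.seed(92)
  for (i in 1:150) {
    pat <- random_prosite_pattern()
    pep <- random_peptide(sample(8:25, 1))
    if (runif(1) < 0.5) {
      inst <- nrunigene:::pattern_instance(pat)
      pos <- sample(nchar(pep) + 1, 1)
      pep <- paste0(substr(pep, 1, pos - 1), inst,
                    substr(pep, pos, nchar(pep)))
    }
    got <- scan_protein(pat, pep)
    exp <- oracle_scan(pat, pep)
    expect_equal(got$start, exp$start)
    expect_equal(got$end, exp$end)
  }
})

test_that("identify_ugt_candidates uses motif and homology evidence", {
  set.seed(93)
  pattern <- default_pspg_pattern()
  inst <- nrunigene:::pattern_instance(pattern)
  pos_seq <- nrunigene:::planted_transcript("complete", 150L, 90L, 240L,
                                            motif_peptide = inst)
  neg_seq <- nrunigene:::planted_transcript("complete", 150L, 90L, 240L)
  ts <- transcript_set(c("pos", "neg"), c(pos_seq, neg_seq))
  orfs <- classify_orf_set(ts, 100L)$orfs
  cand <- identify_ugt_candidates(ts, orfs, pattern)
  expect_equal(cand$transcript_id, "pos")
  expect_equal(cand$evidence, "motif")
  # homology evidence adds but never removes candidates (monotonicity)
  hom <- data.frame(query_id = "neg", subject_id = "UGT73",
                    identity_pct = 85, align_len = 200, evalue = 1e-20,
                    bitscore = 200, stringsAsFactors = FALSE)
  cand2 <- identify_ugt_candidates(ts, orfs, pattern, hom)
  expect_true(all(cand$transcript_id %in% cand2$transcript_id))
  expect_setequal(cand2$transcript_id, c("pos", "neg"))
  expect_equal(cand2$evidence[cand2$transcript_id == "neg"], "homology")
  # six-frame fallback finds motifs without a reported ORF
  cand3 <- identify_ugt_candidates(ts, NULL, pattern)
  expect_true("pos" %in% cand3$transcript_id)
})

test_that("group_pathway_genes counts copies and conserves assignments", {
  ko <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t4", "t5", "t5"),
    ko = c("K00021", "K00021", "K00626", "K99999", "K00511", "K00511"),
    pathway = NA_character_, stringsAsFactors = FALSE)
  def <- list(HMGR = "K00021", AACT = "K00626", SE = "K00511")
  pg <- group_pathway_genes(ko, def)
  expect_equal(pg$copy_count[pg$enzyme_label == "HMGR"], 2L)
  expect_equal(pg$copy_count[pg$enzyme_label == "AACT"], 1L)
  expect_equal(pg$copy_count[pg$enzyme_label == "SE"], 1L)  # distinct only
  expect_equal(attr(pg, "total_transcripts"), 4L)           # t4 ignored
  # empty table -> all groups empty
  pg0 <- group_pathway_genes(ko[0, ], def)
  expect_true(all(pg0$copy_count == 0L))
  expect_equal(attr(pg0, "total_transcripts"), 0L)
  expect_error(group_pathway_genes(ko, list(HMGR = character(0))),
               "no KO ids")
})

test_that("the fixture pathway structure mirrors the multiplicity plan", {
  fx <- generate_fixture(fixture_config(seed = 23), withr::local_tempdir())
  pg <- group_pathway_genes(fx$objects$ko_table,
                            default_pathway_definition())
  expect_equal(attr(pg, "total_transcripts"), 38L)
  copies <- table(pg$copy_count)
  expect_equal(as.integer(copies[c("2", "3", "4")]), c(6L, 2L, 2L))
  expect_equal(sum(pg$copy_count > 1L), 10L)
  expect_equal(sum(pg$copy_count[pg$copy_count > 1L]), 26L)
  # conservation: sum of copy counts equals distinct assignments
  expect_equal(sum(pg$copy_count),
               nrow(unique(fx$objects$ko_table[c("transcript_id", "ko")])))
})
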