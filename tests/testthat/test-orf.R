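nonstop_run <- function(n) {
  set.seed(n)  # deterministic filler of sense codons, no ATG
  pool <- setdiff(nrunigene:::SENSE_CODONS, "ATG")
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

test_that("constructed completeness categories are recognised", {
  # ATG + 100 non-stop codons + TAA -> complete, 101 aa
  comp <- paste0("ATG", nonstop_run(100), "TAA")
  got <- find_best_orf(list(id = "c", sequence = comp), 100L)
  expect_equal(got$category, "complete")
  expect_equal(got$aa_length, 101L)
  expect_true(got$has_start_codon && got$has_stop_codon)
  expect_equal(got$start, 0L)
  expect_equal(got$end, nchar(comp))      # includes the stop codon
  expect_equal((got$end - got$start) %% 3, 0)
  expect_match(got$peptide, "^M")

  # 101 non-stop codons then TAA, no ATG -> five_prime_partial
  fp <- paste0(nonstop_run(101), "TAA")
  gfp <- find_best_orf(list(id = "f", sequence = fp), 100L)
  expect_equal(gfp$category, "five_prime_partial")
  expect_equal(gfp$aa_length, 101L)

  # ATG + run to the edge -> three_prime_partial
  tp <- paste0("TAGTAG", "ATG", nonstop_run(110))
  gtp <- find_best_orf(list(id = "t", sequence = tp), 100L)
  expect_equal(gtp$category, "three_prime_partial")
  expect_false(gtp$has_stop_codon)

  # edge-to-edge run without start or stop -> internal
  int <- nonstop_run(120)
  gint <- find_best_orf(list(id = "i", sequence = int), 100L)
  expect_equal(gint$category, "internal")
})

test_that("short sequences and N-containing codons behave as specified", {
  expect_null(find_best_orf(list(id = "s", sequence = strrep("A", 250)),
                            100L))
  # a TAN codon is not a stop; ANG is not a start
  seq_n <- paste0("ATG", nonstop_run(50), "TAN", nonstop_run(60), "TAA")
  got <- find_best_orf(list(id = "n", sequence = seq_n), 100L)
  expect_equal(got$category, "complete")
  expect_equal(got$aa_length, 112L)  # TAN translates (as X) inside the ORF
})

test_that("find_best_orf agrees with the exhaustive enumeration oracle", {
  set.seed(83)
  for (i in 1:80) {
    s <- random_dna_string(sample(200:2500, 1), with_n = (i %% 5 == 0))
    got <- find_best_orf(list(id = "r", sequence = s), 100L)
    exp <- oracle_best_orf(s, 100L)
    expect_equal(is.null(got), is.null(exp))
    if (is.null(got)) next
    expect_equal(got$aa_length, exp$aa)
    expect_equal(got$frame, exp$frame)
    expect_equal(got$start, exp$start)
    expect_equal(got$end, exp$end)
    expect_equal(got$category, exp$category)
  }
})

test_that("reverse complement mirrors the reported ORF", {
  set.seed(84)
  mirror <- c(`+1` = "-1", `+2` = "-2", `+3` = "-3",
              `-1` = "+1", `-2` = "+2", `-3` = "+3")
  done <- 0
  while (done < 40) {
    s <- random_dna_string(sample(400:2500, 1))
    got <- find_best_orf(list(id = "a", sequence = s), 100L)
    if (is.null(got)) next
    exp <- oracle_best_orf(s, 100L)
    rev <- find_best_orf(list(id = "b", sequence = nrunigene:::revcomp(s)),
                         100L)
    expect_equal(rev$aa_length, got$aa_length)
    if (isTRUE(exp$unique_max)) {
      expect_equal(rev$frame, unname(mirror[got$frame]))
      expect_equal(rev$start, nchar(s) - got$end)
      expect_equal(rev$end, nchar(s) - got$start)
      expect_equal(rev$category, got$category)
    }
    done <- done + 1
  }
})

test_that("classify_orf_set summarises coding and completeness fractions", {
  ts <- transcript_set(
    c("c1", "f1", "t1", "none"),
    c(paste0("ATG", nonstop_run(100), "TAA"),
      paste0(nonstop_run(101), "TAA"),
      paste0("TAGTAG", "ATG", nonstop_run(110)),
      strrep("TAATTAA", 60)))
  res <- classify_orf_set(ts, 100L)
  expect_equal(res$summary$coding_fraction, 0.75)
  expect_equal(res$summary$fraction_complete, 1 / 3)
  expect_equal(res$summary$fraction_5partial, 1 / 3)
  expect_equal(res$summary$fraction_3partial, 1 / 3)
  expect_equal(res$summary$fraction_internal, 0)
  expect_equal(res$summary$fraction_complete + res$summary$fraction_5partial +
                 res$summary$fraction_3partial +
                 res$summary$fraction_internal, 1)
  all_c <- transcript_set(c("x", "y"),
                          rep(paste0("ATG", nonstop_run(100), "TAA"), 2))
  expect_equal(classify_orf_set(all_c, 100L)$summary$fraction_complete, 1)
  expect_error(classify_orf_set(ts[0, ], 100L), "empty")
})

test_that("fixture-planted ORF categories are recovered exactly", {
  fx <- generate_fixture(fixture_config(seed = 19, n_loci = 12,
                                        n_unaligned_components = 4),
                         withr::local_tempdir())
  tr <- fx$objects$transcripts
  truth <- fx$truth$planted_category
  reps <- tr[tr$id %in% names(truth), , drop = FALSE]
  res <- classify_orf_set(reps, 100L)
  got <- stats::setNames(res$orfs$category, res$orfs$transcript_id)
  expect_equal(got[names(truth)], truth)
})
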