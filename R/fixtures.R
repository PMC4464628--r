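# --- deterministic RNG scope -------------------------------------------------

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# --- sequence builders -------------------------------------------------------

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))

# First sense codon per amino acid, for reverse-translating motif peptides.
AA_TO_CODON <- local({
  gc <- Biostrings::GENETIC_CODE
  tapply(names(gc), gc, `[`, 1L)
})

# sample() treats a length-1 numeric as 1:x; this picks from the set as-is.
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Random filler interleaved with a stop-rich block every ~50 bp. The block
# length (7) is not a multiple of 3, so successive insertions cycle through
# the reading frames and long spurious ORFs become very unlikely; planted
# structure is verified after assembly regardless.
stopweave <- function(len) {
  block <- "TAATTAA"
  out <- character(0)
  remaining <- len
  while (remaining > 0L) {
    chunk <- min(43L, remaining)
    out <- c(out, random_dna(chunk))
    remaining <- remaining - chunk
    if (remaining > 0L) {
      b <- substring(block, 1L, min(7L, remaining))
      out <- c(out, b)
      remaining <- remaining - nchar(b)
    }
  }
  paste(out, collapse = "")
}

random_sense_codons <- function(n, first_not_atg = FALSE) {
  cod <- sample(SENSE_CODONS, n, replace = TRUE)
  while (first_not_atg && n > 0L && cod[1L] == "ATG") {
    cod[1L] <- sample(SENSE_CODONS, 1L)
  }
  cod
}

# Build a transcript sequence with a planted best ORF of known completeness
# category; returns NULL when the construction cannot be verified (caller
# resamples).
build_planted_transcript <- function(category, aa, lead_len, trail_len,
                                     motif_peptide = NULL) {
  stopcod <- sample(c("TAA", "TAG", "TGA"), 1L)
  orf_codons <- switch(category,
    complete = c("ATG", random_sense_codons(aa - 1L)),
    five_prime_partial = random_sense_codons(aa, first_not_atg = TRUE),
    three_prime_partial = c("ATG", random_sense_codons(aa - 1L)),
    internal = random_sense_codons(aa, first_not_atg = TRUE))
  if (!is.null(motif_peptide)) {
    res <- strsplit(motif_peptide, "")[[1L]]
    mot <- unname(AA_TO_CODON[res])
    at <- max(2L, aa - length(mot) - 5L)   # keep first codon untouched
    orf_codons[at:(at + length(mot) - 1L)] <- mot
  }
  orf <- paste(orf_codons, collapse = "")
  seq <- switch(category,
    complete = paste0(stopweave(lead_len), orf, stopcod,
                      stopweave(trail_len)),
    five_prime_partial = paste0(orf, stopcod, stopweave(trail_len)),
    three_prime_partial = paste0(stopweave(lead_len), orf),
    internal = orf)
  rec <- list(id = "probe", sequence = seq)
  got <- find_best_orf(rec, min_orf_aa = 100L)
  if (is.null(got) || got$category != category || got$aa_length != aa) {
    return(NULL)
  }
  if (!is.null(motif_peptide) &&
      !grepl(motif_peptide, got$peptide, fixed = TRUE)) {
    return(NULL)
  }
  seq
}

planted_transcript <- function(category, aa, lead_len, trail_len,
                               motif_peptide = NULL, max_tries = 60L) {
  for (i in seq_len(max_tries)) {
    s <- build_planted_transcript(category, aa, lead_len, trail_len,
                                  motif_peptide)
    if (!is.null(s)) return(s)
  }
  stop("failed to construct a verified ", category,
       " transcript in ", max_tries, " tries")
}

# A concrete peptide instance of a PROSITE pattern (minimal repeat counts).
pattern_instance <- function(pattern) {
  if (is.character(pattern)) pattern <- parse_prosite(pattern)
  paste(vapply(pattern$elements, function(el) {
    ch <- switch(el$kind,
                 wildcard = sample(AA20, 1L),
                 literal = el$residues,
                 class = el$residues[1L],
                 negated = setdiff(AA20, el$residues)[1L])
    paste(rep(ch, el$min), collapse = "")
  }, character(1)), collapse = "")
}

# --- fixture configuration ---------------------------------------------------

#' Configuration of the synthetic study generator
#'
#' Defaults state the emulated study design: four root-tissue groups with
#' three biological replicates each, negative-binomial counts with
#' dispersion 0.1 around log-normal baseline abundances (meanlog log(50),
#' sdlog 1), a 10-fold planted differential-expression effect, and
#' genomic loci separated by gaps that make locus clustering unambiguous.
#'
#' @param seed integer RNG seed; identical seeds give byte-identical
#'   bundles.
#' @param n_loci number of genome-anchored gene loci.
#' @param isoforms_per_locus inclusive range (length-2 integer) of isoform
#'   counts per locus.
#' @param locus_gap_bp genomic gap between neighbouring loci (> 0).
#' @param n_unaligned_components number of assembler components with no
#'   genome placement.
#' @param unaligned_isoforms inclusive range of isoforms per unaligned
#'   component.
#' @param n_contaminants,n_rrna,n_lncrna decoy transcript counts.
#' @param groups named integer vector, group label -> replicate count.
#' @param nb_dispersion NB dispersion phi (variance mu + phi mu^2).
#' @param de_fraction,de_fold fraction of unigenes with a planted fold
#'   change, and the fold (> 1).
#' @param specific_fraction fraction of unigenes planted as
#'   tissue-specific.
#' @param n_motif_positives unigenes carrying the glycosyltransferase
#'   signature in their ORF peptide.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline abundance.
#' @param pattern PROSITE pattern string planted and scanned (default: the
#'   package's synthetic PSPG-style stand-in signature).
#' @return validated `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, n_loci = 40L,
                           isoforms_per_locus = c(2L, 4L),
                           locus_gap_bp = 500L,
                           n_unaligned_components = 8L,
                           unaligned_isoforms = c(1L, 3L),
                           n_contaminants = 6L, n_rrna = 4L, n_lncrna = 4L,
                           groups = c(whole_root_1y = 3L, main_body_6y = 3L,
                                      lateral_root_6y = 3L,
                                      rhizome_6y = 3L),
                           nb_dispersion = 0.1, de_fraction = 0.05,
                           de_fold = 10, specific_fraction = 0.05,
                           n_motif_positives = NULL,
                           baseline_meanlog = log(50), baseline_sdlog = 1,
                           target_library_size = 2e5,
                           pattern = default_pspg_pattern()) {
  if (is.null(n_motif_positives)) {
    n_motif_positives <- min(7L, as.integer(n_loci))
  }
  cfg <- list(seed = as.integer(seed), n_loci = as.integer(n_loci),
              isoforms_per_locus = as.integer(isoforms_per_locus),
              locus_gap_bp = as.integer(locus_gap_bp),
              n_unaligned_components = as.integer(n_unaligned_components),
              unaligned_isoforms = as.integer(unaligned_isoforms),
              n_contaminants = as.integer(n_contaminants),
              n_rrna = as.integer(n_rrna), n_lncrna = as.integer(n_lncrna),
              groups = groups, nb_dispersion = nb_dispersion,
              de_fraction = de_fraction, de_fold = de_fold,
              specific_fraction = specific_fraction,
              n_motif_positives = as.integer(n_motif_positives),
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              target_library_size = target_library_size, pattern = pattern)
  stopifnot(cfg$locus_gap_bp > 0L, cfg$n_loci >= 0L,
            cfg$n_unaligned_components >= 0L, cfg$n_contaminants >= 0L,
            cfg$n_rrna >= 0L, cfg$n_lncrna >= 0L,
            length(cfg$isoforms_per_locus) == 2L,
            cfg$isoforms_per_locus[1L] >= 1L,
            diff(cfg$isoforms_per_locus) >= 0L,
            cfg$nb_dispersion >= 0, cfg$de_fold > 1,
            cfg$de_fraction >= 0, cfg$de_fraction <= 1,
            cfg$specific_fraction >= 0, cfg$specific_fraction <= 1,
            length(cfg$groups) >= 1L, all(cfg$groups >= 1L),
            !is.null(names(cfg$groups)))
  class(cfg) <- "fixture_config"
  cfg
}

#' The package's synthetic PSPG-style signature pattern
#'
#' A compact PROSITE-syntax stand-in for the plant secondary product
#' glycosyltransferase signature, used by the fixture generator and the
#' examples. It is synthetic: for real screening, supply the PROSITE
#' PS00375 pattern text as config (see `inst/extdata/`).
#'
#' @return pattern string.
#' @export
default_pspg_pattern <- function() {
  "[FW]-x(2)-[NQS]-G-x(2,3)-[LIVM]-x-H-C-G-W-[NS]-S"
}

# --- count simulation --------------------------------------------------------

#' Simulate a replicate count matrix with planted structure
#'
#' Baseline per-transcript means are log-normal; replicate counts are
#' negative-binomial draws (`variance = mu + phi * mu^2`; `phi = 0` gives
#' Poisson). Planted differentially expressed transcripts have their mean
#' multiplied by `de_fold` in their target group. Planted tissue-specific
#' transcripts get means calibrated from the expected library size so that
#' group-mean FPKM comfortably exceeds 3 in the target group
#' (`specific_fpkm_hi`) and stays well under 1 elsewhere
#' (`specific_fpkm_lo`).
#'
#' @param transcript_ids character vector.
#' @param lengths named or positional vector of transcript lengths (bp).
#' @param groups named integer vector, group -> replicate count.
#' @param nb_dispersion NB dispersion.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline.
#' @param de_fold fold change of planted DE transcripts.
#' @param planted_de,planted_specific named character vectors mapping
#'   transcript id -> target group.
#' @param specific_fpkm_hi,specific_fpkm_lo calibration targets for
#'   planted specific transcripts.
#' @param target_library_size expected fragments per sample: baseline
#'   means keep their log-normal shape but are rescaled so each library
#'   totals about this many fragments. Toy studies have few transcripts;
#'   without this depth floor, FPKM-scale effects would drown in count
#'   discreteness that real libraries do not exhibit.
#' @return a [count_matrix()]; the expected mean matrix is in attribute
#'   `mean_matrix`.
#' @export
simulate_counts <- function(transcript_ids, lengths, groups,
                            nb_dispersion = 0.1,
                            baseline_meanlog = log(50),
                            baseline_sdlog = 1, de_fold = 10,
                            planted_de = character(0),
                            planted_specific = character(0),
                            specific_fpkm_hi = 30,
                            specific_fpkm_lo = 0.02,
                            target_library_size = 2e5) {
  n <- length(transcript_ids)
  stopifnot(length(lengths) == n, all(groups >= 1L))
  samples <- unlist(lapply(names(groups), function(g) {
    paste0(g, "_rep", seq_len(groups[[g]]))
  }))
  group_of <- rep(names(groups), times = groups)
  names(group_of) <- samples

  base <- stats::rlnorm(n, baseline_meanlog, baseline_sdlog)
  if (sum(base) > 0 && !is.null(target_library_size)) {
    base <- base * target_library_size / sum(base)
  }
  mu <- matrix(base, n, length(samples),
               dimnames = list(transcript_ids, samples))
  for (id in names(planted_de)) {
    mu[id, group_of == planted_de[[id]]] <-
      mu[id, group_of == planted_de[[id]]] * de_fold
  }
  if (length(planted_specific)) {
    mu[names(planted_specific), ] <- 0
    lib <- colSums(mu)                      # expected size w/o specifics
    len <- lengths
    names(len) <- transcript_ids
    for (id in names(planted_specific)) {
      tgt <- group_of == planted_specific[[id]]
      mu[id, tgt] <- specific_fpkm_hi * (len[id] / 1e3) * (lib[tgt] / 1e6)
      mu[id, !tgt] <- specific_fpkm_lo * (len[id] / 1e3) * (lib[!tgt] / 1e6)
    }
  }
  draws <- if (nb_dispersion == 0) {
    stats::rpois(length(mu), lambda = mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion)
  }
  counts <- matrix(as.numeric(draws), n, length(samples),
                   dimnames = dimnames(mu))
  out <- count_matrix(counts, group_of)
  attr(out, "mean_matrix") <- mu
  out
}

# --- default pathway definition ---------------------------------------------

#' Default ginsenoside-pathway enzyme definition
#'
#' Curated enzyme label -> KEGG orthology map covering the MVA and MEP
#' isoprenoid pathways and the downstream triterpene steps (squalene
#' epoxidase, beta-amyrin synthase, dammarenediol synthase, the
#' protopanaxadiol/-triol CYP450s). Shipped as editable config in
#' `inst/extdata/pathway_definition.tsv`.
#'
#' @return named list enzyme label -> KO ids.
#' @export
default_pathway_definition <- function() {
  read_pathway_definition(system.file("extdata", "pathway_definition.tsv",
                                      package = "nrunigene",
                                      mustWork = TRUE))
}

# Multiplicity structure planted on pathway enzymes: six enzymes in two
# copies, two in three, two in four (26 multi-copy transcripts), remainder
# single-copy.
pathway_copy_plan <- function(labels) {
  plan <- stats::setNames(rep(1L, length(labels)), labels)
  two <- intersect(c("AACT", "HMGS", "MK", "DXS", "SE", "SS"), labels)
  three <- intersect(c("HMGR", "Beta-AS"), labels)
  four <- intersect(c("FPS", "IDI"), labels)
  plan[two] <- 2L
  plan[three] <- 3L
  plan[four] <- 4L
  plan
}

# --- the generator -----------------------------------------------------------

#' Generate a complete synthetic study bundle
#'
#' Emits, under `outdir`, every input the pipeline consumes — genome and
#' transcript FASTA, GMAP-style alignment GFF3, contaminant/protein hit
#' tables, rRNA predictions, a replicate count matrix with sample-group
#' map, a KO table and pathway definition, and the signature pattern —
#' plus machine-readable truth tables under `outdir/truth/`. Identical
#' seeds give byte-identical bundles.
#'
#' Constructed properties: isoforms of a locus are 3'-truncations of the
#' locus transcript (so clustering and longest-member selection have
#' unambiguous truth); every planted ORF and motif is re-verified during
#' construction; decoys (contaminant, rRNA, long-noncoding) are flagged in
#' the evidence tables and recorded in the truth bundle.
#'
#' @param config a [fixture_config()].
#' @param outdir output directory (created; files are overwritten).
#' @return (invisibly) list with `paths` (named file paths), `truth`
#'   (truth tables as R objects) and `config`.
#' @export
generate_fixture <- function(config = fixture_config(), outdir) {
  stopifnot(inherits(config, "fixture_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  with_seed(config$seed, generate_fixture_impl(config, outdir))
}

generate_fixture_impl <- function(cfg, outdir) {
  ids <- character(0)
  seqs <- character(0)
  categories <- character(0)   # per planted full-length transcript
  pattern <- parse_prosite(cfg$pattern)

  # -- genome-anchored loci --------------------------------------------------
  n_per_scaffold <- 10L
  scaffold_of <- sprintf("scaffold_%02d",
                         ((seq_len(cfg$n_loci) - 1L) %/% n_per_scaffold) + 1L)
  locus_component <- sprintf("Pg_Root%06d_c0", 100000L + seq_len(cfg$n_loci))
  cat_pool <- c("complete", "five_prime_partial", "three_prime_partial",
                "internal")
  cat_prob <- c(0.60, 0.19, 0.10, 0.11)

  # Motif positives live on locus representatives (the full-length isoform).
  motif_loci <- integer(0)
  if (cfg$n_motif_positives > 0L) {
    if (cfg$n_motif_positives > cfg$n_loci) {
      stop("n_motif_positives exceeds n_loci")
    }
    motif_loci <- sort(sample(cfg$n_loci, cfg$n_motif_positives))
  }

  genome <- list()
  aln_id <- character(0)
  aln_scaf <- character(0)
  aln_strand <- character(0)
  aln_exons <- list()
  locus_of <- character(0)
  expected_reps <- character(0)
  planted_motif <- character(0)
  planted_category <- character(0)

  cursor <- stats::setNames(rep(0L, length(unique(scaffold_of))),
                            unique(scaffold_of))
  for (k in seq_len(cfg$n_loci)) {
    category <- sample(cat_pool, 1L, prob = cat_prob)
    aa <- sample(130:300, 1L)
    motif_pep <- if (k %in% motif_loci) pattern_instance(pattern) else NULL
    lead <- 3L * sample(30:80, 1L)
    trail <- 3L * sample(150:400, 1L)
    full <- planted_transcript(category, aa, lead, trail, motif_pep)
    len_full <- nchar(full)

    n_iso <- sample1(seq(cfg$isoforms_per_locus[1L],
                         cfg$isoforms_per_locus[2L]))
    # 3' truncations; for edge-ending categories keep the cut tiny so the
    # planted ORF stays >= 100 aa, otherwise cut inside the trailing filler.
    max_cut <- if (category %in% c("three_prime_partial", "internal")) {
      min(trail, 3L * (aa - 110L))
    } else {
      trail - 30L
    }
    cuts <- if (n_iso > 1L) {
      sort(sample(seq(10L, max(11L, max_cut)), n_iso - 1L))
    } else integer(0)

    scaf <- scaffold_of[k]
    gstart <- cursor[scaf] + cfg$locus_gap_bp
    intron <- random_dna(80L)
    exon1_len <- 150L
    genome[[scaf]] <- paste0(genome[[scaf]] %||% "",
                             random_dna(cfg$locus_gap_bp),
                             substring(full, 1L, exon1_len), intron,
                             substring(full, exon1_len + 1L))
    cursor[scaf] <- gstart + len_full + 80L

    iso_lens <- c(len_full, len_full - cuts)
    strand <- sample(c("+", "-"), 1L)
    for (j in seq_len(n_iso)) {
      iso_id <- sprintf("%s_seq%d", locus_component[k], j)
      iso_len <- iso_lens[j]
      ids <- c(ids, iso_id)
      seqs <- c(seqs, substring(full, 1L, iso_len))
      locus_of[iso_id] <- locus_component[k]
      aln_id <- c(aln_id, iso_id)
      aln_scaf <- c(aln_scaf, scaf)
      aln_strand <- c(aln_strand, strand)
      e1 <- c(gstart, gstart + exon1_len)
      e2 <- c(gstart + exon1_len + 80L, gstart + 80L + iso_len)
      aln_exons <- c(aln_exons, list(rbind(e1, e2)))
    }
    rep_id <- sprintf("%s_seq1", locus_component[k])
    expected_reps <- c(expected_reps, rep_id)
    planted_category[rep_id] <- category
    if (!is.null(motif_pep)) planted_motif <- c(planted_motif, rep_id)
  }

  # -- unaligned components --------------------------------------------------
  for (u in seq_len(cfg$n_unaligned_components)) {
    comp <- sprintf("Pg_Root%06d_c0", 200000L + u)
    category <- sample(cat_pool, 1L, prob = cat_prob)
    aa <- sample(120:250, 1L)
    lead <- 3L * sample(20:60, 1L)
    trail <- 3L * sample(100:250, 1L)
    full <- planted_transcript(category, aa, lead, trail)
    n_iso <- sample1(seq(cfg$unaligned_isoforms[1L],
                         cfg$unaligned_isoforms[2L]))
    max_cut <- if (category %in% c("three_prime_partial", "internal")) {
      min(trail, 3L * (aa - 110L))
    } else {
      trail - 30L
    }
    cuts <- if (n_iso > 1L) {
      sort(sample(seq(10L, max(11L, max_cut)), n_iso - 1L))
    } else integer(0)
    iso_lens <- c(nchar(full), nchar(full) - cuts)
    for (j in seq_len(n_iso)) {
      iso_id <- sprintf("%s_seq%d", comp, j)
      ids <- c(ids, iso_id)
      seqs <- c(seqs, substring(full, 1L, iso_lens[j]))
      locus_of[iso_id] <- comp
    }
    rep_id <- sprintf("%s_seq1", comp)
    expected_reps <- c(expected_reps, rep_id)
    planted_category[rep_id] <- category
  }

  # -- decoys ----------------------------------------------------------------
  contam_ids <- sprintf("Pg_Contam%03d_c0_seq1", seq_len(cfg$n_contaminants))
  contam_seqs <- vapply(seq_len(cfg$n_contaminants),
                        function(i) random_dna(sample(500:1200, 1L)),
                        character(1))
  rrna_ids <- sprintf("Pg_Rrna%03d_c0_seq1", seq_len(cfg$n_rrna))
  rrna_seqs <- vapply(seq_len(cfg$n_rrna),
                      function(i) random_dna(sample(800:1800, 1L)),
                      character(1))
  lnc_ids <- sprintf("Pg_Lnc%03d_c0_seq1", seq_len(cfg$n_lncrna))
  lnc_seqs <- vapply(seq_len(cfg$n_lncrna), function(i) {
    for (try in 1:60) {
      s <- stopweave(sample(450:700, 1L))
      if (is.null(find_best_orf(list(id = "x", sequence = s), 100L))) {
        return(s)
      }
    }
    stop("failed to construct an ORF-free noncoding decoy")
  }, character(1))

  ids <- c(ids, contam_ids, rrna_ids, lnc_ids)
  seqs <- c(seqs, contam_seqs, rrna_seqs, lnc_seqs)
  transcripts <- transcript_set(ids, seqs)

  # Contaminant hits: strong hits on decoys, weak ones on a few real
  # transcripts (must be kept).
  hit_row <- function(q, s, ident, alen, ev, bits) {
    sprintf("%s\t%s\t%.1f\t%d\t0\t0\t1\t%d\t1\t%d\t%.2g\t%.1f",
            q, s, ident, alen, alen, alen, ev, bits)
  }
  contam_lines <- vapply(seq_along(contam_ids), function(i) {
    len <- nchar(contam_seqs[i])
    hit_row(contam_ids[i], sprintf("microbe_%02d", i), 98.2,
            as.integer(0.9 * len), 1e-80, 600)
  }, character(1))
  weak_targets <- utils::head(expected_reps, 3L)
  weak_lines <- vapply(seq_along(weak_targets), function(i) {
    hit_row(weak_targets[i], "microbe_weak", 82.0, 60L, 1e-3, 45)
  }, character(1))

  # rRNA predictions: near-full coverage on decoys, a small fragment on one
  # real transcript (must be kept).
  rrna_pred <- data.frame(
    transcript_id = rrna_ids,
    start = 0L,
    end = as.integer(0.9 * nchar(rrna_seqs)),
    score = round(stats::runif(cfg$n_rrna, 40, 90), 1))
  if (length(expected_reps)) {
    frag_id <- expected_reps[1L]
    frag_len <- transcripts$length[match(frag_id, transcripts$id)]
    rrna_pred <- rbind(rrna_pred, data.frame(
      transcript_id = frag_id, start = 0L,
      end = as.integer(0.1 * frag_len), score = 21.5))
  }

  # Protein homology: every real (locus/unaligned) transcript has a hit;
  # noncoding decoys have none.
  real_ids <- setdiff(ids, c(contam_ids, rrna_ids, lnc_ids))
  prot_lines <- vapply(seq_along(real_ids), function(i) {
    hit_row(real_ids[i], sprintf("sprot_%05d", i), 88.0, 300L, 1e-30, 250)
  }, character(1))

  # -- alignments ------------------------------------------------------------
  alignments <- alignment_set(
    aln_id, aln_scaf, aln_strand, aln_exons,
    identity_pct = round(stats::runif(length(aln_id), 96.5, 100), 1),
    coverage_pct = round(stats::runif(length(aln_id), 95, 100), 1))

  # -- counts over the Nr representative set ---------------------------------
  rep_lengths <- transcripts$length[match(expected_reps, transcripts$id)]
  n_rep <- length(expected_reps)
  n_de <- floor(cfg$de_fraction * n_rep)
  n_sp <- floor(cfg$specific_fraction * n_rep)
  pool <- sample(expected_reps)
  de_ids <- utils::head(pool, n_de)
  sp_ids <- utils::head(setdiff(pool, de_ids), n_sp)
  planted_de <- stats::setNames(
    sample(names(cfg$groups), n_de, replace = TRUE), de_ids)
  planted_specific <- stats::setNames(
    sample(names(cfg$groups), n_sp, replace = TRUE), sp_ids)
  counts <- simulate_counts(expected_reps, rep_lengths, cfg$groups,
                            nb_dispersion = cfg$nb_dispersion,
                            baseline_meanlog = cfg$baseline_meanlog,
                            baseline_sdlog = cfg$baseline_sdlog,
                            de_fold = cfg$de_fold,
                            planted_de = planted_de,
                            planted_specific = planted_specific,
                            target_library_size = cfg$target_library_size)

  # -- KO table over representatives ----------------------------------------
  definition <- default_pathway_definition()
  plan <- pathway_copy_plan(names(definition))
  ko_pool <- setdiff(expected_reps, character(0))
  ko_rows <- list()
  taken <- 0L
  for (lab in names(definition)) {
    n_copy <- plan[[lab]]
    avail <- min(n_copy, length(ko_pool) - taken)
    if (avail <= 0L) break
    picked <- ko_pool[(taken + 1L):(taken + avail)]
    taken <- taken + avail
    ko_rows[[lab]] <- data.frame(transcript_id = picked,
                                 ko = definition[[lab]][1L],
                                 pathway = "ginsenoside_biosynthesis",
                                 stringsAsFactors = FALSE)
  }
  ko_table <- if (length(ko_rows)) do.call(rbind, ko_rows) else
    data.frame(transcript_id = character(0), ko = character(0),
               pathway = character(0), stringsAsFactors = FALSE)
  rownames(ko_table) <- NULL

  # -- write the bundle ------------------------------------------------------
  p <- function(...) file.path(outdir, ...)
  genome_set <- Biostrings::BStringSet(unlist(genome))
  Biostrings::writeXStringSet(genome_set, p("genome.fa"))
  write_fasta(transcripts, p("transcripts.fa"))
  write_alignments_gff3(alignments, p("alignments.gff3"))
  writeLines(c(contam_lines, weak_lines), p("contaminant_hits.tsv"))
  writeLines(prot_lines, p("protein_hits.tsv"))
  utils::write.table(rrna_pred, p("rrna_predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_count_matrix(counts, p("counts.tsv"))
  utils::write.table(
    data.frame(sample = names(counts$groups), group = counts$groups),
    p("sample_groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ko_table, p("ko.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  file.copy(system.file("extdata", "pathway_definition.tsv",
                        package = "nrunigene", mustWork = TRUE),
            p("pathway_definition.tsv"), overwrite = TRUE)
  writeLines(cfg$pattern, p("pspg_pattern.txt"))

  tw <- function(df, name) {
    utils::write.table(df, p("truth", name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tw(data.frame(transcript_id = names(locus_of), group_id = locus_of),
     "locus_of_transcript.tsv")
  tw(data.frame(transcript_id = expected_reps),
     "expected_representatives.tsv")
  tw(data.frame(transcript_id = names(planted_de), group = planted_de),
     "planted_de.tsv")
  tw(data.frame(transcript_id = names(planted_specific),
                group = planted_specific), "planted_specific.tsv")
  tw(data.frame(transcript_id = planted_motif), "planted_motif.tsv")
  tw(data.frame(transcript_id = names(planted_category),
                category = planted_category), "planted_category.tsv")
  tw(data.frame(transcript_id = c(contam_ids, rrna_ids, lnc_ids),
                decoy_type = rep(c("contaminant", "rrna", "lncrna"),
                                 c(length(contam_ids), length(rrna_ids),
                                   length(lnc_ids)))), "decoys.tsv")

  truth <- list(locus_of_transcript = locus_of,
                expected_representatives = expected_reps,
                planted_de = planted_de,
                planted_specific = planted_specific,
                planted_motif = planted_motif,
                planted_category = planted_category,
                decoys = list(contaminant = contam_ids, rrna = rrna_ids,
                              lncrna = lnc_ids))
  paths <- list(genome = p("genome.fa"), transcripts = p("transcripts.fa"),
                alignments = p("alignments.gff3"),
                contaminant_hits = p("contaminant_hits.tsv"),
                protein_hits = p("protein_hits.tsv"),
                rrna_predictions = p("rrna_predictions.tsv"),
                counts = p("counts.tsv"),
                sample_groups = p("sample_groups.tsv"),
                ko = p("ko.tsv"),
                pathway_definition = p("pathway_definition.tsv"),
                pattern = p("pspg_pattern.txt"),
                truth_dir = p("truth"))
  invisible(list(paths = paths, truth = truth, config = cfg,
                 objects = list(transcripts = transcripts,
                                alignments = alignments, counts = counts,
                                ko_table = ko_table)))
}
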