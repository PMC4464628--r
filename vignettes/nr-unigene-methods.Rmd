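---
title: "Methods: non-redundant unigene construction and root transcriptome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-redundant unigene construction and root transcriptome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`nrunigene` turns a redundant de novo transcriptome assembly into a
non-redundant (Nr) unigene set by anchoring transcripts to reference
genome scaffolds, and provides the downstream analyses a multi-tissue
expression study needs: ORF completeness, FPKM-based differential
expression and tissue-specificity calling, glycosyltransferase motif
screening, and pathway gene grouping. This vignette documents the model
behind each stage, the tunable parameters with their defaults, the
numerical choices that fix behaviour at the edges, and what the
synthetic fixtures do and do not establish.

## The cleanup cascade

De novo assemblies of field-grown plant tissue mix genuine mRNA with
rRNA, microbial transcripts and long noncoding RNA. The cascade removes
these in a fixed order — contaminants, then rRNA, then noncoding — and
attributes every removed transcript to the first stage that caught it,
so the report categories partition the removed set and the identity
`final = initial − Σ removed` always holds.

* **Contaminants.** A transcript is removed when one hit against the
  contaminant database passes all of: e-value ≤ `1e-10`, identity ≥
  90 %, aligned length ≥ 50 % of the transcript. The thresholds are
  deliberately conservative (a weak local hit to a microbial genome is
  common for low-complexity sequence) and all configurable.
* **rRNA.** A transcript is removed when the interval union of its rRNA
  predictions covers ≥ 50 % of its length. The union (not the sum)
  matters when predictions overlap; a partial rRNA fragment in a
  UTR-like region does not trigger removal.
* **Noncoding.** A transcript is flagged when it has no ORF of ≥ 100
  amino acids and no protein hit at e-value ≤ `1e-5`. Published
  noncoding pipelines add coding-potential scores with tool-specific
  parameters that are not reproducible here; this package deliberately
  re-specifies the criterion as the conjunction of two testable
  absences and says so prominently. A transcript with either kind of
  coding evidence is never flagged.

## Locus clustering and representative selection

Transcript-to-genome placements are screened at read time (defaults:
identity ≥ 95 %, coverage ≥ 90 %; the identity default is the common
screening value for high-quality same-species alignments, the coverage
default is this package's choice since no canonical value exists).
Retained placements are clustered per scaffold and strand by single
linkage: two placements link when their genomic spans overlap by at
least `min_overlap_bp` (default 1 bp — any overlap). Span-based
(intron-spanning) overlap is used because the unit being reconstructed
is the gene locus, not the shared exonic base; an exon-level mode would
split genes whose isoforms share no exon, which is not what locus
collapsing intends.

Clustering is strand-aware by default so antisense overlapping genes
stay distinct; a merged-strand mode exists because fragmented scaffold
assemblies sometimes carry unreliable strand assignments.

A transcript whose placements fall into different clusters is assigned
to the cluster of its best placement — highest identity, then longest
span, then lexicographically smallest scaffold and start. Chimeric and
duplicated placements have no principled resolution at this level; the
tie-break is chosen for determinism, not biology, and multi-placement
transcripts are surfaced by the reader so callers can apply their own
policy.

Each locus contributes its **longest member** as the unigene
representative (ties: lexicographically smallest id in the C locale).
Length is the only selection signal the collapsing strategy defines;
exon-chain consensus assembly is explicitly out of scope. Unaligned
transcripts are grouped by their assembler component id
(`<stem>_seq<k>`), again keeping the longest member. A read-depth
filter for unaligned components is not implemented — the upstream
procedure it would emulate is not reproducible from published
parameters — but the collapse function is a clean seam where an
external depth filter can be applied first.

Assembly statistics follow the standard definitions; N50 is the
smallest member length L such that members ≥ L hold at least half of
the total bases.

## ORF discovery and completeness

All six frames are scanned. Candidate ORFs are maximal runs of
non-stop codons that begin at an ATG or at the frame's 5′ edge and end
at a stop (TAA/TAG/TGA) or the 3′ edge; runs that begin right after a
stop without an ATG are not candidates. Codons containing ambiguity
symbols never match start or stop. The reported ORF is the candidate
with the most amino acids at or above the 100-aa floor; ties resolve by
frame order (+1, +2, +3, −1, −2, −3), then 5′-most start. The
amino-acid count excludes the stop codon; coordinates are 0-based
half-open on the forward strand, and a stop codon, when present, is
inside the reported interval (so `end − start = 3·aa + 3` for
stop-terminated ORFs).

Completeness is relative to the transcript edges: complete (start and
stop), 5′-partial (stop only), 3′-partial (start only), internal
(neither). Only the standard genetic code is used and only ATG counts
as a start — alternative starts would change the completeness
accounting in ways the collapsing strategy never relies on. Homology
rescue of sub-threshold ORFs is supported only through an external
evidence table; no coding-potential model is trained.

## Expression model

FPKM is `count / ((L/10³)·(libsize/10⁶))` with the transcript length as
effective length: the fragment-length correction belongs to the
upstream quantifier, which is out of scope, so the identity stays exact
and testable. Group means are arithmetic means over replicate FPKM
columns.

**Differential expression.** The engine is an exact conditional test
under a negative-binomial model with a common dispersion φ (variance
μ + φμ²). With groups of n_a and n_b replicates at a common library
size, the group-A sum conditioned on the pooled total follows a
negative hypergeometric law with shape parameters n_a/φ and n_b/φ —
independent of the NB probability parameter — and φ = 0 recovers the
conditional binomial of the Poisson model. The two-sided p-value sums
the probabilities of all outcomes no more likely than the observed one.
This is a self-contained simplification of the quasi-likelihood /
empirical-Bayes machinery of the established DE packages: the decision
rule being reproduced is the thresholding (FDR ≤ 0.01 via
Benjamini–Hochberg, fold change ≥ 2), not a particular dispersion
shrinkage estimator. Numerical choices fixed once:

* Library equalization scales each sample to the geometric-mean library
  size and rounds to the nearest integer (conditional tests need
  integers; deterministic rounding fixes tests).
* The common dispersion, when not supplied, is the median of
  per-transcript method-of-moments estimates `(var − mean)/mean²`.
* log₂ fold changes use group means of equalized counts with a
  pseudo-count of 1 fragment, avoiding infinities at zero.
* "FDR up to 0.01" and "fold change of 2" are both read as inclusive
  bounds (`fdr ≤ 0.01`, `|log2FC| ≥ 1`); the specificity thresholds
  are strict (`> 3`, `< 1`) because they are stated as strict
  inequalities.

**Tissue specificity.** A transcript is specific to a group when its
group-mean FPKM is strictly above 3 there and strictly below 1 in every
other group; with hi ≥ lo at most one group can qualify.

**Co-expression** is the Pearson correlation of log₂(FPKM + 1) across
all samples; the default reporting cutoff |r| ≥ 0.9 is a stringent
conventional value for candidate prioritisation (no canonical value is
stated for this analysis). Zero-variance transcripts are skipped with a
warning rather than producing NaN.

## Motif engine and pathway grouping

The PROSITE-syntax engine supports literals, classes `[..]`, negated
classes `{..}`, the wildcard `x`, fixed and bounded repeats, and
terminal anchors. Scanning reports, per admissible start position, the
shortest match (variable repeats expand minimally); this fixes a single
deterministic disambiguation instead of enumerating all expansions.
`X` in a peptide matches only wildcard positions, and `*` (a stop in a
six-frame translation) matches nothing, so motifs cannot span stops.

Glycosyltransferase candidates are transcripts whose best-ORF peptide
(or any six-frame translation, for transcripts without a reported ORF)
contains the signature, or that hit a reference UGT collection at
e-value ≤ `1e-5` when a homology table is supplied — so adding homology
evidence is monotone. The original screening was homology-based against
signature-bearing reference sequences; direct pattern scanning is
deterministic and database-free, which is why this package scans. The
shipped pattern file is a synthetic stand-in (labelled so); the real
PS00375 definition should be supplied as config for real screening.

Pathway grouping joins a transcript→KO table against an enzyme→KO
definition (editable TSV; the shipped default covers the MVA and MEP
isoprenoid pathways and the downstream triterpene steps). Copy counts
are distinct transcripts per enzyme, so Σ copy_count equals the number
of distinct (transcript, enzyme) assignments.

## The synthetic study generator

The generator emits a complete toy study with machine-readable truth:
a scaffold genome, loci whose isoforms are 3′ truncations of one
transcript (so clustering truth and the longest-member rule are
unambiguous by construction), unaligned components, decoys flagged in
evidence tables, exact GFF3 placements, and a replicate count matrix.
Its defaults are the stated world of the emulated design: four tissue
groups × three biological replicates, NB dispersion 0.1, log-normal
baseline abundances (meanlog log 50, sdlog 1), planted 10-fold DE
effects, specificity effects calibrated to FPKM ≈ 30 vs ≈ 0.02, loci
separated by 500-bp gaps.

Two constructive details matter:

* **Stop-weave filler.** Non-ORF sequence is random DNA interleaved
  with a stop-rich 7-mer every ~50 bp; because 7 ≢ 0 (mod 3) the
  insertions cycle the reading frames, making long spurious ORFs very
  unlikely. Every planted ORF, category and motif is nevertheless
  re-verified at generation time (with rejection sampling), so truth
  tables are guaranteed consistent. The verification uses the package's
  own ORF finder; its correctness is established independently by
  exhaustive-enumeration oracle tests.
* **Depth floor.** Baseline means keep their log-normal shape but are
  rescaled so each library totals ~2×10⁵ expected fragments. A toy
  study with 50 transcripts would otherwise have libraries of a few
  thousand fragments, where an expected FPKM of 30 is a fractional
  count and FPKM-scale effects drown in discreteness real libraries do
  not exhibit.

What a green test establishes — and what it does not: the fixtures
exercise truncation-structured isoforms, well-separated loci, exact
alignments and NB counts with a common dispersion. They do not emulate
alternative splicing graphs, chimeric or duplicated placements,
fragment-length bias, transcript-assignment uncertainty in counting, or
tagwise dispersion variation; conclusions about those phenomena cannot
be drawn from these tests.

## Degenerate inputs and tie-breaks (summary)

Empty transcript sets error in summarising operations and return empty
results in collapsing ones; a sequence shorter than 3×100 nt yields "no
ORF" rather than an error; both-groups-all-zero counts give p = 1;
all-identical groups give p = 1; spans shorter than `min_overlap_bp`
can never link and form singleton loci. All order-dependent selections
(representatives, top-abundance ties, co-expression output) break ties
lexicographically in the C locale for cross-platform determinism.

## Known limitations

* The noncoding criterion is a stated stand-in, not a reimplementation
  of any published coding-potential pipeline.
* The DE engine's common dispersion ignores mean-dependent dispersion
  trends; with strongly varying tagwise dispersion its error control is
  approximate (the acceptance tests verify calibration only at a common
  dispersion).
* FPKM uses transcript length as effective length; comparisons across
  transcripts of very different lengths inherit the usual FPKM caveats.
* Library equalization is total-count scaling. On panels with few
  transcripts, a strongly regulated transcript is a large fraction of
  its library and total-count scaling spuriously shifts every other
  transcript in that sample (composition bias); trimmed or
  median-of-ratios normalisation is out of scope. With realistically
  sized transcript panels the effect is negligible.
* The unaligned-component collapse implements length selection only; no
  read-depth evidence is consulted.
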