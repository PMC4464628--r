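Package: nrunigene
Title: Non-Redundant Unigene Construction and Root Transcriptome Profiling
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for reducing redundancy in de novo assembled plant
    transcriptomes by anchoring transcripts to a reference genome. Implements
    the post-assembly cleanup cascade (contaminant, rRNA and long-noncoding
    removal from evidence tables), single-linkage clustering of genome-aligned
    transcripts into gene loci with length-based representative selection,
    assembler-component collapsing of unaligned transcripts, six-frame ORF
    discovery with completeness classification, FPKM quantification, an exact
    negative-binomial conditional test for differential expression with
    Benjamini-Hochberg control, tissue-specificity calling, PROSITE-syntax
    motif scanning for glycosyltransferase discovery, KEGG-orthology pathway
    gene grouping, and a deterministic synthetic-study generator with
    machine-readable truth tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
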