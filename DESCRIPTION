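Package: hapiso
Title: Variant-Aware Isoform Detection and A-to-I Editing Analytics for
    Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotation-reliant assignment of long cDNA reads to transcript
    models with splice-site fidelity checks, collapse of unassigned reads
    into novel isoforms, ploidy-agnostic calling of haplotype-specific
    transcripts from per-read variant combinations, and long-read A-to-I
    editing analytics (differential editing after ADAR knockdown, type I/II
    hyperediting, single-molecule co-editing, and edit/splice mutual
    exclusivity). Includes a deterministic long-read simulator that emits
    reads with ground-truth alignments so every stage can be exercised
    without an external aligner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    vcfR,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
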