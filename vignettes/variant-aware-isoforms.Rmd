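---
title: "Variant-aware isoform detection and editing analytics with hapiso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant-aware isoform detection and editing analytics with hapiso}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapiso)
```

## What the package does

Long cDNA reads can span whole transcripts, which makes three things
possible that short reads do poorly: deciding which annotated isoform a
read really supports (including its splice sites and both ends), detecting
unannotated isoforms from full-length evidence, and reading out the *cis*
configuration of sequence variants and RNA edits along single molecules.
`hapiso` implements that workflow: annotation-reliant read-to-transcript
assignment with splice-fidelity rules, collapse of unassigned reads into
novel isoform models, ploidy-agnostic haplotype-specific transcript (HST)
calling, and A-to-I (inosine) editing analytics over a two-condition ADAR
knockdown design. A read simulator with ground-truth alignments makes the
whole pipeline testable without an external aligner.

All internal coordinates are 0-based half-open; conversion to GTF/VCF
1-based conventions happens only inside the parsers and writers.

## Read-to-transcript assignment

A read aligned to a transcript sequence is scored by `compute_fidelity()`:

* **match fraction** — matched bases over aligned read bases (insertions
  count against the denominator, soft clips are excluded — "percent of
  bases matching" with an explicit denominator choice);
* **end coverage** — whether the alignment starts within 25 bp of the
  transcript 5' end and ends within 25 bp of the 3' end, so a supporting
  read must span into the first and last exons. Both bounds are inclusive:
  a read starting exactly 25 bp in still passes;
* **per-junction quality** — for every splice junction, how many of the six
  flanking bases (three per side) are matched, and the largest indel whose
  footprint touches that window.

`passes_stringent()` requires a match fraction of at least 0.8 *and* both
end flags; `passes_check_splice()` requires at least 4 of 6 flanking bases
matched and no indel larger than 3 bp at *every* junction. A junction that
the alignment does not cover fails the read for that transcript: read-level
evidence must span the entire isoform, which deliberately sacrifices
sensitivity on very long transcripts for precision. `assign_read()`
evaluates all candidates tied at the maximum mapping quality and keeps the
passing candidate with the highest match fraction (ties: more matched
bases, then smallest transcript id — fully deterministic).

Rather than invoking an aligner, `assign_to_annotation()` *projects* each
read's genomic alignment through every compatible transcript's exon
structure (`project_to_transcript()`): a candidate is valid only if every
read junction matches a model junction exactly, and bases beyond the model
span are clipped. Alignments produced by an external aligner against
transcript sequences can be supplied instead via `read_sam_alignments()`;
use `=`/`X` CIGAR operators (minimap2 `--eqx`) so mismatches are scored.

## Novel isoform collapse

Reads that support no annotated transcript go through the collapse branch:

1. **Junction correction** (`correct_junctions()`): each junction boundary
   is kept if it occurs in the evidence set (annotation and, optionally,
   short-read junctions) or snapped to the nearest evidence boundary within
   10 bp; a boundary with no evidence in range rejects the read. The
   alignment is rewritten so a snapped boundary shows up as an indel of the
   shift size at the splice site — so at realignment the splice check
   effectively tolerates shifts up to 3 bp.
2. **Grouping** (`group_by_junction_chain()`): exact junction-chain
   equality. Single-exon reads are clustered per locus by 50% reciprocal
   overlap (single linkage) — the chain key does not apply to them.
3. **End calling** (`call_ends()`): 5' start and 3' end positions are
   clustered with single linkage at a 100 bp fuzzy window; each cluster is
   represented by its most frequent position, at most two TSS and two TES
   clusters are kept per chain, and a (TSS, TES) pairing is emitted only if
   at least one read is consistent with both (pairing by co-occurrence, not
   the full cross product).
4. **Finalisation** (`finalize_isoforms()`): reads are realigned (by
   projection) to the first-pass isoforms under the same fidelity rules;
   isoforms keeping at least 3 reads survive. Novel ids are
   `<junction-chain hash>_<gene-or-locus>` and stable across runs. Strand
   is inferred from splice-site dinucleotides (GT..AG / CT..AC) when a
   genome is supplied, else from the majority read strand.

`detect_isoforms()` chains the two branches and returns the merged model
set, the read map, and the reads supporting nothing. Defaults: correction
window 10 bp, end window 100 bp, minimum support 3 reads — the first two
are unstated upstream and configurable here; 3 supporting reads matches
the tool family's default.

## Haplotype-specific transcripts

Two modalities associate variants with isoforms.

**Ploidy-agnostic tabulation.** `profile_reads()` records, for each
supporting read of an isoform, the base observed at every SNV inside the
isoform's exons (`ref`, `alt`, or `uncovered` for a third base, a deletion,
a spliced-out or unreached position). `tabulate_haplotypes()` counts exact
allele vectors over reads covering every site and retains vectors with at
least 3 reads *and* at least 10% of the isoform's reads — thresholds
mirroring the isoform support default, chosen because "sufficient support"
is otherwise unquantified. There is deliberately no ploidy cap: RNA edits
and aneuploid tumours produce more than two consistent haplotypes. A read
with uncovered sites is folded into a retained haplotype only when exactly
one is compatible, and discarded otherwise — partial vectors are never
created, which keeps 3'-truncated reads from fragmenting true haplotypes.

**Phase-set mode** (`phase_set_mode()`): when a diploid phasing caller has
tagged reads with phase set (`PS`) and haplotype (`HP`), an isoform is
linked to a (phase set, haplotype) if a strict majority (> 0.5) of its
tagged reads agree, and the phase set's variants inside the isoform's
exons are attached.

`hst_bias_test()` asks, per variant and isoform, whether the allele balance
differs from the pooled balance of the gene's other isoforms: a two-sided
Fisher exact test on `[[ref, alt in isoform], [ref, alt in others]]`,
Benjamini–Hochberg adjusted across all tests (the adjustment method is
recorded in the output header), significant below 0.05. Degenerate tables
(any zero margin) get p = 1 and a flag rather than an error. The test is
per variant — matching the per-variant output table layout — even when
several variants phase together.

`emit_hst_outputs()` writes the variant-substituted isoform FASTA
(complementing alternate alleles on minus-strand isoforms), a BED12 model
file and a VCF whose `ISO=` INFO key names the isoforms carrying each
variant.

## Inosine editing analytics

A-to-I editing is read as A>G on the transcribed strand, so
`candidate_inosines()` keeps A>G calls in forward-strand genes and T>C
calls in reverse-strand genes, resolving strand against the gene
annotation and dropping ambiguous or unannotated sites. `pileup_counts()`
tallies, per site, edited and reference reads per condition (replicates
summed), excludes other bases and deletions from both counts, and counts
reads whose alignment splices the site out. Downstream:

* `differential_editing()` — Fisher exact per site on the knockdown vs
  control counts, kept when coverage ≥ 10 in *either* condition (the rule
  is a disjunction), |edited-fraction change| ≥ 10%, raw p < 0.05 (no
  multiple-testing correction: corrected p-values leave too few
  discoveries at long-read depths, so discovery uses raw p), with the
  direction of change recorded.
* `classify_type1()` — a site is type I hyperedited when strictly more
  than 40% of its covering reads are edited.
* `type2_regions()` — regions with ≥ 3 edits within every 150 bp. The
  candidate windows are anchored at sites (any qualifying window can be
  slid right to a site without losing sites); overlapping qualifying
  windows merge into maximal regions whose bounds are the outermost sites.
* `coordination_test()` — for pairs of sites at least 50 bp apart (each
  site paired with its up-to-20 nearest eligible neighbours; the union of
  directed neighbourhoods, each unordered pair tested once), a Fisher test
  on the per-molecule 2x2 of edited/unedited status at the two sites;
  pairs with p < 0.05 are reported as co-edited.
* `intron_editing()` — sites that are type I in the control condition with
  ≥ 10 edited reads and ≥ 10 spliced-out reads: candidate positions where
  editing and splicing are mutually exclusive on single molecules.
  "Spliced out" requires the site strictly inside an intron operation.

## The simulator: what it emulates and what it does not

`make_transcriptome()` builds a random genome with embedded multi-isoform
genes (exon skipping and alternative donors/acceptors; canonical GT..AG
motifs planted at the full isoform's junctions so strand is recoverable).
`simulate_reads()` draws reads per isoform per haplotype with i.i.d.
per-base errors at the configured accuracy (substitution : insertion :
deletion = 50 : 25 : 25) and optional 3'-anchored geometric truncation,
and — the design decision that makes the package self-contained — emits
every read with its ground-truth transcript- and genome-space alignment,
so fidelity scoring, pileups and profiles run without minimap2. The
default accuracy of 0.99 reflects rolling-circle consensus reads, the
regime the ploidy-agnostic haplotype caller is designed for; it is *not*
robust to raw-read error rates, where spurious allele vectors would
accumulate.

The error model is intentionally simpler than a trained nanopore
simulator: no homopolymer bias, glitches, junk/chimera reads, or
quality-correlated errors. Passing tests therefore demonstrate the logic
of the method under calibrated noise, not robustness to every artefact of
real flowcells. Junction coordinates in simulated reads are exact, so the
junction-correction path is exercised by constructed perturbations rather
than by the simulator.

`simulate_editing_experiment()` plants transcribed-strand A positions,
edits each read independently at each site with the condition's fraction,
and supports intron-retention isoforms so that the same position is edited
on retaining molecules and spliced out on others. Replicates per condition
are generated separately and pooled by `pileup_counts()`, mirroring a
combined-replicate knockdown design.

## Numerical and design choices

* **Inclusive boundaries.** 0.80 match passes; indel of exactly 3 bp
  passes; a read reaching exactly 25 bp from a transcript end passes.
  "Larger than 3 bp" fixes the indel bound; the match-fraction bound is
  inclusive for symmetry.
* **Tie-breaks** are deterministic everywhere: assignment prefers more
  matched bases then the smallest transcript id; junction snapping prefers
  the smaller shift then the leftmost boundary; end clusters prefer the
  most frequent position then the smallest coordinate, and equally
  supported clusters the smaller representative.
* **Degenerate tables** give p = 1 with a flag (no information, not an
  error); zero-coverage edit fractions are 0 with a flag.
* **Fisher tests** use the exact conditional test throughout
  (`fisher2x2()`, one shared core). The exact test is conservative at low
  counts: its size is about 0.040 at 100 reads per condition and 0.047 at
  1000. The null-calibration check therefore runs at 1000 reads per
  condition over 400 sites — the coverage regime where nominal and actual
  levels agree — and the knockdown-recovery check uses 30x coverage per
  replicate with three replicates per condition pooled, the combined-
  replicate design under which the full filter chain has exact power
  0.9999 for a 0.6 to 0.2 drop (at a strict single 30x condition it would
  be 0.85).
* **Problem sizes in the test-suite** are chosen to exercise each claim at
  desk scale: the multi-haplotype construct uses one gene, three isoforms,
  15 variants in three disjoint haplotypes at 20x per haplotype and 99%
  accuracy; collapse idempotence uses 50 transcripts at 3 error-free reads
  each; the Fisher core is swept exhaustively against an enumeration
  oracle for all tables up to N = 60.

## Worked example

```{r example, eval = FALSE}
library(hapiso)

ex <- hst_example(seed = 1)   # 3 isoforms x 3 haplotypes x 20 reads
ex$n_recovered                # 15: all planted variants in correct HSTs
head(ex$groups[, c("isoform_id", "haplotype", "support")])

counts <- hst_counts_from_profiles(ex$profiles, ex$txome$models)
res <- hst_bias_test(counts)
subset(res, significant)
```

## Known limitations

* Realignment is projection-based and exact on junctions; a read whose
  corrected junctions still differ from every model is unassignable even
  if an affine aligner would rescue it.
* `M` CIGAR runs from external aligners are scored as matches; supply
  `--eqx`-style alignments for meaningful fidelity thresholds.
* Single-exon isoform calling uses reciprocal-overlap clustering only; no
  TSS/TES validation against external 5'/3' evidence is implemented.
* The HST bias test treats reads as independent; PCR duplicates would
  inflate significance.
* Editing analytics assume SNV-style edit evidence; clustered edits that
  break alignment upstream of this package are invisible to it.
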