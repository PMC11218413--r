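#' Multi-haplotype HST benchmark construct
#'
#' A hand-built gene for exercising ploidy-agnostic haplotype calling beyond
#' the diploid case: one forward-strand gene with five 200-bp exons and three
#' isoforms (full length; exon 3 skipped; short 3' end stopping after exon
#' 4), carrying `n_variants` SNVs spread over the exons shared by all three
#' isoforms (minimum spacing 20 bp), partitioned into three disjoint
#' haplotypes (variants 1..k on haplotype A, and so on). Reads are simulated
#' per haplotype per isoform and the full variant-to-isoform assignment is
#' run.
#'
#' @param seed Integer seed for the read simulation (the gene structure and
#'   variant placement are fixed).
#' @param n_variants Number of planted SNVs (default 15; must be divisible
#'   by 3).
#' @param coverage Reads per haplotype per isoform (default 20).
#' @param accuracy Per-base accuracy (default 0.99).
#' @return List with the simulation inputs (`txome`, `variants`,
#'   `haplotypes`) and outputs (`sim`, `read_map`, `profiles`, `groups`)
#'   plus `n_recovered`, the number of planted variants incorporated into a
#'   correct haplotype-specific transcript (see [score_hst_recovery()]).
#' @export
hst_example <- function(seed = 1L, n_variants = 15L, coverage = 20L,
                        accuracy = 0.99) {
  stopifnot(n_variants %% 3 == 0)
  set.seed(.subseed(seed, 10L))
  exlen <- 200L; inlen <- 150L
  starts <- 100L + (0:4) * (exlen + inlen)
  exons <- cbind(starts, starts + exlen)
  glen <- max(exons) + 100L
  gseq <- sample(.DNA, glen, replace = TRUE)
  for (k in 1:4) {  # canonical motifs at the full isoform's gaps
    d <- exons[k, 2]; a <- exons[k + 1, 1]
    gseq[c(d + 1, d + 2)] <- c("G", "T")
    gseq[c(a - 1, a)] <- c("A", "G")
  }
  genome <- Biostrings::DNAStringSet(setNames(paste(gseq, collapse = ""),
                                              "chr1"))
  models <- list(
    tx1 = transcript_model("tx1", "geneA", "chr1", "+", exons),
    tx2 = transcript_model("tx2", "geneA", "chr1", "+", exons[-3, ]),
    tx3 = transcript_model("tx3", "geneA", "chr1", "+", exons[1:4, ]))

  # variants in exons 1, 2 and 4 (shared by all three isoforms), 20 bp apart
  per_exon <- n_variants / 3L
  vpos <- c(exons[1, 1] + 20L * seq_len(per_exon),
            exons[2, 1] + 20L * seq_len(per_exon),
            exons[4, 1] + 20L * seq_len(per_exon))
  ref <- gseq[vpos + 1L]
  alt <- vapply(ref, function(r) sample(setdiff(.DNA, r), 1), "")
  variants <- data.frame(chrom = "chr1", pos = vpos, ref = ref,
                         alt = unname(alt), phase_set = NA_character_,
                         stringsAsFactors = FALSE)
  vkeys <- paste0("chr1:", vpos)
  third <- n_variants / 3L
  haplotypes <- list(hapA = vkeys[seq_len(third)],
                     hapB = vkeys[third + seq_len(third)],
                     hapC = vkeys[2L * third + seq_len(third)])

  cfg <- sim_config(seed = seed, per_base_accuracy = accuracy,
                    coverage_per_haplotype = coverage)
  txome <- list(genome = genome, models = models, cfg = cfg,
                truth = data.frame(
                  transcript_id = names(models), gene_id = "geneA",
                  strand = "+",
                  chain = vapply(models, junction_chain, ""),
                  stringsAsFactors = FALSE, row.names = NULL))
  sim <- simulate_reads(txome, variants, haplotypes, cfg)

  assignments <- assign_to_annotation(sim$genomic_alns, models)
  ann <- supported_annotated_isoforms(assignments)
  profiles <- profile_reads(ann$supported, variants, sim$genomic_alns,
                            models)
  groups <- tabulate_all_haplotypes(profiles)
  n_rec <- score_hst_recovery(groups, variants, haplotypes, models)
  list(txome = txome, variants = variants, haplotypes = haplotypes,
       sim = sim, read_map = ann$supported, profiles = profiles,
       groups = groups, n_recovered = n_rec)
}

#' Score recovery of planted variants in HST output
#'
#' A planted variant counts as recovered when some isoform whose exons
#' contain it has a retained haplotype group that (a) carries the variant's
#' alternate allele and (b) matches one of the planted allele vectors
#' exactly over all of that isoform's variant sites (no spurious co-alleles).
#'
#' @param groups `data.frame` from [tabulate_all_haplotypes()].
#' @param variants Planted variant `data.frame`.
#' @param haplotypes Named list of alt-variant-key vectors (as given to
#'   [simulate_reads()]).
#' @param models Named list of [transcript_model()].
#' @return Integer: number of planted variants correctly incorporated.
#' @export
score_hst_recovery <- function(groups, variants, haplotypes, models) {
  vkeys <- paste0(variants$chrom, ":", variants$pos)
  recovered <- logical(length(vkeys))
  for (gi in seq_len(nrow(groups))) {
    al <- groups$alleles[[gi]]
    # planted truth restricted to this isoform's variant set
    planted_ok <- any(vapply(haplotypes, function(hk) {
      expect <- ifelse(names(al) %in% hk, "alt", "ref")
      all(al == expect)
    }, TRUE))
    if (!planted_ok) next
    hit <- names(al)[al == "alt"]
    recovered[match(hit, vkeys)] <- TRUE
  }
  sum(recovered)
}
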