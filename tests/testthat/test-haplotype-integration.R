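# Variant-to-isoform profiles, ploidy-agnostic haplotypes, phase-set mode,
# HST bias testing, HST output writers.

# one 2-exon plus-strand model and fully-matching reads with chosen bases
hap_fixture <- function(read_bases, exlen = 50L) {
  m <- toy_model(cbind(c(0L, 100L), c(exlen, 100L + exlen)))
  # variants at genomic 10 and 110 (both exonic)
  v <- data.frame(chrom = "chr1", pos = c(10L, 110L), ref = c("A", "C"),
                  alt = c("G", "T"), phase_set = NA_character_)
  alns <- list()
  for (i in seq_along(read_bases)) {
    rb <- read_bases[[i]]
    seq1 <- paste(rep("A", exlen), collapse = "")
    seq2 <- paste(rep("C", exlen), collapse = "")
    substr(seq1, 11, 11) <- rb[1]
    substr(seq2, 11, 11) <- rb[2]
    rid <- paste0("r", i)
    alns[[rid]] <- mk_aln(c(match = exlen, intron = 50, match = exlen),
                          start = 0L, kind = "genome", target = "chr1",
                          id = rid, seq = paste0(seq1, seq2))
  }
  list(m = m, v = v, alns = alns,
       read_map = list(tx1 = names(alns)), models = list(tx1 = m))
}

test_that("profiles record ref/alt/uncovered per the read base", {
  fx <- hap_fixture(list(c("G", "T"), c("A", "C"), c("N", "C")))
  pr <- profile_reads(fx$read_map, fx$v, fx$alns, fx$models)$tx1
  expect_equal(unname(pr$obs[1, ]), c("alt", "alt"))
  expect_equal(unname(pr$obs[2, ]), c("ref", "ref"))
  expect_equal(unname(pr$obs[3, ]), c("uncovered", "ref"))
})

test_that("deletions and spliced positions are uncovered; variants outside
           exons are excluded", {
  fx <- hap_fixture(list(c("A", "C")))
  # read with a deletion spanning genomic 10
  del <- mk_aln(c(match = 5, deletion = 10, match = 35, intron = 50,
                  match = 50), start = 0L, kind = "genome", target = "chr1",
                id = "rdel",
                seq = paste(c(rep("A", 40), rep("C", 50)), collapse = ""))
  alns <- c(fx$alns, list(rdel = del))
  rm <- list(tx1 = c("r1", "rdel"))
  pr <- profile_reads(rm, fx$v, alns, fx$models)$tx1
  expect_equal(unname(pr$obs["rdel", 1]), "uncovered")
  # an intronic variant is dropped from the isoform's variant set
  v2 <- rbind(fx$v, data.frame(chrom = "chr1", pos = 75L, ref = "A",
                               alt = "G", phase_set = NA))
  expect_message(pr2 <- profile_reads(rm, v2, alns, fx$models)$tx1,
                 "outside exons")
  expect_equal(nrow(pr2$variants), 2)
})

test_that("all four read bases map to ref/alt/uncovered correctly", {
  for (b in c("A", "C", "G", "T")) {
    fx <- hap_fixture(list(c(b, "C")))
    pr <- profile_reads(fx$read_map, fx$v, fx$alns, fx$models)$tx1
    want <- if (b == "A") "ref" else if (b == "G") "alt" else "uncovered"
    expect_equal(unname(pr$obs[1, 1]), want)
  }
})

test_that("haplotype tabulation keeps well-supported vectors, any number of
           them, and folds partial reads uniquely", {
  obs <- rbind(matrix(rep(c("alt", "alt"), 10), ncol = 2, byrow = TRUE),
               matrix(rep(c("ref", "ref"), 5), ncol = 2, byrow = TRUE),
               matrix(rep(c("alt", "ref"), 4), ncol = 2, byrow = TRUE),
               matrix(rep(c("ref", "alt"), 2), ncol = 2, byrow = TRUE))
  colnames(obs) <- c("chr1:10", "chr1:110")
  rownames(obs) <- paste0("r", seq_len(nrow(obs)))
  pr <- list(isoform_id = "tx1", obs = obs,
             variants = data.frame(chrom = "chr1", pos = c(10L, 110L)))
  hg <- tabulate_haplotypes(pr)
  # support 2 < 3 is not emitted; three haplotypes are (ploidy-agnostic)
  expect_equal(nrow(hg), 3)
  expect_setequal(hg$haplotype, c("alt;alt", "ref;ref", "alt;ref"))
  expect_equal(hg$support[hg$haplotype == "alt;alt"], 10L)

  # a partial read compatible with two retained vectors is discarded
  obs2 <- rbind(obs, rpart = c("alt", "uncovered"))  # alt;alt or alt;ref
  pr2 <- list(isoform_id = "tx1", obs = obs2, variants = pr$variants)
  hg2 <- tabulate_haplotypes(pr2)
  expect_equal(hg2$support[hg2$haplotype == "alt;alt"], 10L)
  expect_equal(hg2$support[hg2$haplotype == "alt;ref"], 4L)
  # one compatible with a single retained vector is folded into it
  # ("ref", uncovered) fits only ref;ref since ref;alt was not retained
  obs3 <- rbind(obs, rpart = c("ref", "uncovered"))
  pr3 <- list(isoform_id = "tx1", obs = obs3, variants = pr$variants)
  hg3 <- tabulate_haplotypes(pr3)
  expect_equal(hg3$support[hg3$haplotype == "ref;ref"], 6L)
})

test_that("min_fraction suppresses rare vectors even above min_support", {
  obs <- rbind(matrix(rep(c("alt", "alt"), 50), ncol = 2, byrow = TRUE),
               matrix(rep(c("ref", "ref"), 4), ncol = 2, byrow = TRUE))
  colnames(obs) <- c("chr1:10", "chr1:110")
  rownames(obs) <- paste0("r", seq_len(nrow(obs)))
  pr <- list(isoform_id = "tx1", obs = obs,
             variants = data.frame(chrom = "chr1", pos = c(10L, 110L)))
  hg <- tabulate_haplotypes(pr)   # 4/54 < 10%
  expect_equal(hg$haplotype, "alt;alt")
  # sum of supports never exceeds the isoform's read count
  expect_lte(sum(hg$support), nrow(obs))
})

test_that("phase-set mode requires a strict majority of tagged reads", {
  fx <- hap_fixture(rep(list(c("A", "C")), 10))
  v <- fx$v
  v$phase_set <- "PS1"
  tag <- function(a, hp) { a$tags <- list(HP = hp, PS = "PS1"); a }
  alns <- fx$alns
  for (i in 1:8) alns[[i]] <- tag(alns[[i]], 1L)
  for (i in 9:10) alns[[i]] <- tag(alns[[i]], 2L)
  res <- phase_set_mode(fx$read_map, alns, v, fx$models)
  expect_equal(res$phase_set, "PS1")
  expect_equal(res$haplotype, "1")
  expect_equal(res$n_linked, 8L)
  expect_length(res$variants[[1]], 2)

  # a 5/5 split fails the strict majority
  for (i in 1:5) alns[[i]] <- tag(alns[[i]], 1L)
  for (i in 6:10) alns[[i]] <- tag(alns[[i]], 2L)
  expect_equal(nrow(phase_set_mode(fx$read_map, alns, v, fx$models)), 0)

  # tags present but the phase set has no variants inside the isoform
  v2 <- v; v2$pos <- c(60L, 70L)   # intronic
  for (i in 1:8) alns[[i]] <- tag(alns[[i]], 1L)
  expect_message(res2 <- phase_set_mode(fx$read_map, alns, v2, fx$models),
                 "no phase-set variant")
  expect_length(res2$variants[[1]], 0)
})

test_that("HST bias test matches enumeration on canonical tables and
           applies BH", {
  counts <- data.frame(
    gene_id = "g", isoform_id = c("i1", "i2"), chrom = "chr1", pos = 10L,
    ref = "A", alt = "G", ref_count = c(5L, 5L), alt_count = c(5L, 5L))
  res <- hst_bias_test(counts)
  expect_equal(res$p_value, c(1, 1))

  counts2 <- data.frame(
    gene_id = "g", isoform_id = c("i1", "i2"), chrom = "chr1", pos = 10L,
    ref = "A", alt = "G", ref_count = c(10L, 0L), alt_count = c(0L, 10L))
  res2 <- hst_bias_test(counts2)
  expect_equal(res2$p_value[1], 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res2$p_value[1], fisher_enum_oracle(10, 0, 0, 10),
               tolerance = 1e-12)

  # BH: {0.01, 0.02, 0.03} -> all 0.03 (step-up by hand)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  # adjusted p is monotone in raw p and bounded by 1
  set.seed(8)
  praw <- runif(20)
  padj <- p.adjust(praw, "BH")
  expect_true(all(diff(padj[order(praw)]) >= 0))
  expect_true(all(padj <= 1))
})

test_that("degenerate margins yield p = 1 with a flag", {
  counts <- data.frame(
    gene_id = "g", isoform_id = c("i1", "i2"), chrom = "chr1", pos = 10L,
    ref = "A", alt = "G", ref_count = c(10L, 8L), alt_count = c(0L, 0L))
  res <- hst_bias_test(counts)
  expect_equal(res$p_value, c(1, 1))
  expect_true(all(res$degenerate))
})

test_that("shared Fisher core equals the enumeration oracle on random
           tables and is symmetric", {
  set.seed(99)
  for (i in 1:200) {
    x <- as.integer(rmultinom(1, sample(4:50, 1), runif(4)))
    p1 <- fisher2x2(x[1], x[2], x[3], x[4])$p
    expect_equal(p1, fisher_enum_oracle(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-12)
    # row swap, column swap and transpose leave p unchanged
    expect_equal(p1, fisher2x2(x[3], x[4], x[1], x[2])$p, tolerance = 1e-12)
    expect_equal(p1, fisher2x2(x[2], x[1], x[4], x[3])$p, tolerance = 1e-12)
    expect_equal(p1, fisher2x2(x[1], x[3], x[2], x[4])$p, tolerance = 1e-12)
  }
})

test_that("HST outputs substitute alleles strand-aware and round-trip", {
  set.seed(12)
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")))
  chr <- as.character(genome[[1]])
  for (strand in c("+", "-")) {
    m <- toy_model(cbind(c(10L, 150L), c(100L, 250L)), strand = strand)
    pos <- 160L
    ref <- substr(chr, pos + 1, pos + 1)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    v <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                    phase_set = NA)
    hg <- data.frame(isoform_id = "tx1", haplotype = "alt", support = 5L)
    hg$alleles <- list(setNames("alt", paste0("chr1:", pos)))
    pre <- file.path(tempdir(), paste0("hst", strand == "+"))
    out <- emit_hst_outputs(hg, list(tx1 = m), v, genome, pre)
    hseq <- as.character(out$sequences[[1]])
    t_off <- genome_to_tx(m, pos)
    want <- if (strand == "-") chartr("ACGT", "TGCA", alt) else alt
    expect_equal(substr(hseq, t_off + 1, t_off + 1), want)
    # everything else is the reference isoform sequence
    refseq <- as.character(transcript_sequences(list(m), genome)[[1]])
    substr(refseq, t_off + 1, t_off + 1) <- want
    expect_equal(hseq, refseq)
    # files exist and the VCF names the HST
    expect_true(all(file.exists(out$paths)))
    vb <- vcfR::read.vcfR(out$paths["vcf"], verbose = FALSE)
    expect_match(vcf_fix1(vb)[["INFO"]], "tx1_hap1")
  }
  # an all-reference haplotype reproduces the reference sequence
  m <- toy_model(cbind(c(10L, 150L), c(100L, 250L)))
  v <- data.frame(chrom = "chr1", pos = 160L, ref = "A", alt = "G",
                  phase_set = NA)
  hg <- data.frame(isoform_id = "tx1", haplotype = "ref", support = 5L)
  hg$alleles <- list(setNames("ref", "chr1:160"))
  out <- emit_hst_outputs(hg, list(tx1 = m), v, genome,
                          file.path(tempdir(), "hstref"))
  expect_equal(as.character(out$sequences[[1]]),
               as.character(transcript_sequences(list(m), genome)[[1]]))
})

test_that("haplotype supports per isoform never exceed its read count on
           simulated data", {
  ex <- hst_example(seed = 6, coverage = 10)
  for (iso in unique(ex$groups$isoform_id)) {
    expect_lte(sum(ex$groups$support[ex$groups$isoform_id == iso]),
               length(ex$read_map[[iso]]))
  }
})
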