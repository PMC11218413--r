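# Junction correction, chain grouping, end calling, finalisation.

ev_from_junctions <- function(donors, acceptors, chrom = "chr1") {
  junction_evidence(junction_bed = data.frame(
    chrom = chrom, start = donors, end = acceptors))
}

test_that("junctions already in evidence are untouched", {
  ev <- ev_from_junctions(200L, 300L)
  a <- mk_aln(c(match = 100, intron = 100, match = 100), start = 100L,
              kind = "genome", target = "chr1")
  ca <- correct_junctions(a, ev)
  expect_equal(ca$ops, a$ops)
  expect_equal(unname(read_junctions(ca)[1, ]), c(200L, 300L))
})

test_that("boundaries snap to the nearest evidence site within the window,
           matching a nearest-neighbour oracle", {
  set.seed(5)
  donors <- sort(sample(1000:5000, 20)) * 2L       # even, well separated
  acceptors <- donors + 500L
  ev <- ev_from_junctions(donors, acceptors)
  for (i in 1:25) {
    d_true <- sample(donors, 1)
    a_true <- d_true + 500L
    off <- sample(-10:10, 1)
    a <- mk_aln(c(match = 100, intron = 500L - off, match = 100),
                start = d_true + off - 100L, kind = "genome",
                target = "chr1")
    # read donor = d_true + off; read acceptor = a_true (in evidence)
    ca <- correct_junctions(a, ev)
    cand <- donors[abs(donors - (d_true + off)) <= 10]
    d_exp <- cand[order(abs(cand - (d_true + off)), cand)][1]  # oracle
    expect_equal(unname(read_junctions(ca)[1, 1]), d_exp)
    # corrected alignment still spans the same read bases
    expect_equal(aln_read_bases(ca), aln_read_bases(a))
  }
})

test_that("a junction with no evidence within the window rejects the read", {
  ev <- ev_from_junctions(200L, 300L)
  a <- mk_aln(c(match = 100, intron = 100, match = 100), start = 115L,
              kind = "genome", target = "chr1")   # donor at 215, 15 bp away
  expect_null(correct_junctions(a, ev))
})

test_that("snapped boundaries appear as splice-site indels of the shift
           size", {
  ev <- ev_from_junctions(200L, 300L)
  # donor at 198 (2 bp early): read lacks 2 reference bases at the site
  a <- mk_aln(c(match = 98, intron = 102, match = 100), start = 100L,
              kind = "genome", target = "chr1")
  ca <- correct_junctions(a, ev)
  expect_equal(unname(read_junctions(ca)[1, ]), c(200L, 300L))
  expect_true(any(ca$ops$op == "deletion" & ca$ops$len == 2))
  # donor at 203 (3 bp late): 3 read bases displaced out of the exon
  b <- mk_aln(c(match = 103, intron = 97, match = 100), start = 100L,
              kind = "genome", target = "chr1")
  cb <- correct_junctions(b, ev)
  expect_equal(unname(read_junctions(cb)[1, ]), c(200L, 300L))
  expect_true(any(cb$ops$op == "insertion" & cb$ops$len == 3))
  expect_equal(aln_read_bases(cb), aln_read_bases(b))
})

test_that("grouping is by exact junction chain; single-exon reads cluster by
           reciprocal overlap", {
  a1 <- mk_aln(c(match = 50, intron = 100, match = 50), start = 100L,
               kind = "genome", target = "chr1", id = "a1")
  a2 <- mk_aln(c(match = 80, intron = 100, match = 20), start = 70L,
               kind = "genome", target = "chr1", id = "a2")
  b1 <- mk_aln(c(match = 50, intron = 120, match = 50), start = 100L,
               kind = "genome", target = "chr1", id = "b1")
  s1 <- mk_aln(c(match = 200), start = 1000L, kind = "genome",
               target = "chr1", id = "s1")
  s2 <- mk_aln(c(match = 200), start = 1050L, kind = "genome",
               target = "chr1", id = "s2")
  s3 <- mk_aln(c(match = 200), start = 5000L, kind = "genome",
               target = "chr1", id = "s3")
  g <- group_by_junction_chain(list(a1, a2, b1, s1, s2, s3))
  expect_length(g, 4)
  sizes <- sort(vapply(g, length, 0L))
  expect_equal(unname(sizes), c(1L, 1L, 2L, 2L))
  expect_length(group_by_junction_chain(list()), 0)
})

test_that("end calling keeps at most two start/end clusters and matches the
           single-linkage oracle on fuzzy starts", {
  mk <- function(start, id) mk_aln(c(match = 100, intron = 100,
                                     match = 2400 - start),
                                   start = start, kind = "genome",
                                   target = "chr1", id = id)
  # five identical starts -> one TSS at 100
  g1 <- lapply(1:5, function(i) mk(100L, paste0("r", i)))
  fp1 <- call_ends(g1)
  expect_length(fp1, 1)
  expect_equal(fp1[[1]]$tss, 100L)

  # starts 100x5, 400x5, 800x5 under window 100: the two biggest kept (all
  # tie at 5; the deterministic rule keeps the two smallest representatives)
  g2 <- c(lapply(1:5, function(i) mk(100L, paste0("a", i))),
          lapply(1:5, function(i) mk(400L, paste0("b", i))),
          lapply(1:5, function(i) mk(800L, paste0("c", i))))
  # junction must sit downstream of all starts: rebuild with intron at 900
  g2 <- lapply(seq_along(g2), function(i) {
    st <- c(rep(100L, 5), rep(400L, 5), rep(800L, 5))[i]
    mk_aln(c(match = 900 - st, intron = 100, match = 500), start = st,
           kind = "genome", target = "chr1", id = paste0("r", i))
  })
  fp2 <- call_ends(g2)
  expect_length(fp2, 2)
  expect_setequal(vapply(fp2, `[[`, 0L, "tss"), c(100L, 400L))

  # 100x3 + 130x2 merge into one cluster represented by the mode 100
  g3 <- lapply(1:5, function(i) {
    st <- c(100L, 100L, 100L, 130L, 130L)[i]
    mk_aln(c(match = 900 - st, intron = 100, match = 500), start = st,
           kind = "genome", target = "chr1", id = paste0("r", i))
  })
  starts <- c(100, 100, 100, 130, 130)
  expect_equal(max(single_linkage_oracle(starts, 100)), 1)  # one cluster
  fp3 <- call_ends(g3)
  expect_length(fp3, 1)
  expect_equal(fp3[[1]]$tss, 100L)
})

test_that("finalisation enforces the support threshold after realignment", {
  cfg <- sim_config(seed = 41, n_genes = 2, isoforms_per_gene = 2,
                    per_base_accuracy = 1, coverage_per_haplotype = 3)
  tx <- make_transcriptome(cfg)
  sim <- simulate_reads(tx, cfg = cfg)
  ev <- junction_evidence(tx$models)
  corr <- Filter(Negate(is.null),
                 lapply(sim$genomic_alns, correct_junctions, evidence = ev))
  groups <- group_by_junction_chain(corr)
  fp <- unlist(lapply(groups, call_ends), recursive = FALSE)
  fin3 <- finalize_isoforms(fp, corr, genome = tx$genome,
                            annotation = tx$models, min_support = 3)
  expect_length(fin3$models, length(tx$models))   # 3 reads each: all kept
  fin4 <- finalize_isoforms(fp, corr, genome = tx$genome,
                            annotation = tx$models, min_support = 4)
  expect_length(fin4$models, 0)                   # 3 reads < 4: all dropped
  # novel ids are stable across runs
  fin3b <- finalize_isoforms(fp, corr, genome = tx$genome,
                             annotation = tx$models, min_support = 3)
  expect_identical(names(fin3$models), names(fin3b$models))
})

test_that("with no unassigned reads the final set is the annotated set", {
  cfg <- sim_config(seed = 43, n_genes = 2, isoforms_per_gene = 2,
                    per_base_accuracy = 1, coverage_per_haplotype = 4)
  tx <- make_transcriptome(cfg)
  sim <- simulate_reads(tx, cfg = cfg)
  res <- detect_isoforms(sim$genomic_alns, tx$models, tx$genome)
  expect_setequal(names(res$isoforms), names(tx$models))
  expect_length(res$unassigned, 0)
})

test_that("collapse is idempotent on error-free reads from hidden
           transcripts and no read supports two isoforms", {
  cfg <- sim_config(seed = 47, n_genes = 5, isoforms_per_gene = 2,
                    per_base_accuracy = 1, coverage_per_haplotype = 3)
  tx <- make_transcriptome(cfg)
  sim <- simulate_reads(tx, cfg = cfg)
  # hide the annotation from assignment: novel path only, evidence = truth
  ev <- junction_evidence(tx$models)
  corr <- Filter(Negate(is.null),
                 lapply(sim$genomic_alns, correct_junctions, evidence = ev))
  groups <- group_by_junction_chain(corr)
  fp <- unlist(lapply(groups, call_ends), recursive = FALSE)
  fin <- finalize_isoforms(fp, corr, genome = tx$genome)
  got <- sort(unname(vapply(fin$models, junction_chain, "")))
  want <- sort(unname(vapply(tx$models, junction_chain, "")))
  expect_equal(got, want)
  expect_false(anyDuplicated(unlist(fin$read_map)) > 0)
  # every final chain is present among the corrected reads' chains
  read_chains <- unique(vapply(corr, function(a) {
    j <- read_junctions(a)
    paste0(a$target_id, ":", paste(paste0(j[, 1], "-", j[, 2]),
                                   collapse = ","))
  }, ""))
  expect_true(all(got %in% read_chains))
  # strand recovered from splice motifs
  st_want <- setNames(vapply(tx$models, `[[`, "", "strand"),
                      vapply(tx$models, junction_chain, ""))
  st_got <- vapply(fin$models, `[[`, "", "strand")
  expect_equal(unname(st_got),
               unname(st_want[vapply(fin$models, junction_chain, "")]))
})
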