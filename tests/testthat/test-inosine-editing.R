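# Inosine candidate filtering, pileup, differential editing, hyperediting,
# coordination and edit/splice exclusivity.

strand_models <- function() {
  list(fw = toy_model(cbind(0L, 1000L), id = "fw", gene = "gfw"),
       rv = toy_model(cbind(2000L, 3000L), strand = "-", id = "rv",
                      gene = "grv"))
}

test_that("candidate sites follow the gene-strand A>G / T>C rule", {
  mods <- strand_models()
  v <- data.frame(chrom = "chr1",
                  pos = c(100L, 2100L, 2200L, 150L, 5000L),
                  ref = c("A", "A", "T", "T", "A"),
                  alt = c("G", "G", "C", "C", "G"),
                  phase_set = NA)
  cand <- candidate_inosines(v, mods)
  # A>G in + gene kept; A>G in - gene dropped; T>C in - gene kept;
  # T>C in + gene dropped; unannotated dropped
  expect_equal(cand$pos, c(100L, 2200L))
  expect_equal(cand$gene_strand, c("+", "-"))
  expect_equal(attr(cand, "n_dropped"), 1)   # the unannotated one
  # known-sites flag
  ks <- data.frame(chrom = "chr1", start = 90L, end = 110L)
  cand2 <- candidate_inosines(v, mods, known_sites = ks)
  expect_equal(cand2$in_known, c(TRUE, FALSE))
})

mk_read <- function(base_at_site, id, site = 100L, start = 50L, len = 100L) {
  seq <- paste(rep("A", len), collapse = "")
  substr(seq, site - start + 1, site - start + 1) <- base_at_site
  mk_aln(c(match = len), start = start, kind = "genome", target = "chr1",
         id = id, seq = seq)
}

test_that("pileup counts edited/unedited, excludes other bases, tallies
           spliced reads and keeps uncovered sites", {
  sites <- data.frame(chrom = "chr1", pos = c(100L, 900L), ref = "A",
                      alt = "G", gene_strand = "+", edited_base = "G")
  ctrl <- c(lapply(1:10, function(i) mk_read("G", paste0("g", i))),
            lapply(1:5, function(i) mk_read("A", paste0("a", i))),
            lapply(1:3, function(i) mk_read("N", paste0("n", i))))
  spliced <- lapply(1:7, function(i)
    mk_aln(c(match = 30, intron = 100, match = 30), start = 50L,
           kind = "genome", target = "chr1", id = paste0("s", i),
           seq = strrep("A", 60)))
  counts <- pileup_counts(list(ctrl = c(ctrl, spliced), kd = list()), sites)
  expect_equal(counts$edited_ctrl[1], 10L)
  expect_equal(counts$unedited_ctrl[1], 5L)
  expect_equal(counts$spliced_out[1], 7L)
  expect_equal(counts$edited_kd[1], 0L)
  # site 900 has no reads at all but is retained with zeros
  expect_equal(counts$edited_ctrl[2] + counts$unedited_ctrl[2] +
                 counts$spliced_out[2], 0L)
})

test_that("differential editing applies the coverage, delta and p filters
           with direction", {
  counts <- data.frame(
    chrom = "chr1", pos = c(1L, 2L, 3L), gene_strand = "+",
    edited_ctrl = c(8L, 5L, 10L), unedited_ctrl = c(2L, 4L, 10L),
    edited_kd = c(1L, 4L, 9L), unedited_kd = c(9L, 5L, 11L),
    spliced_out = 0L)
  de <- differential_editing(counts)
  # site 1: 0.8 -> 0.1, p from the enumeration oracle, down, significant
  expect_equal(de$p_value[1], fisher_enum_oracle(1, 9, 8, 2),
               tolerance = 1e-12)
  expect_true(de$significant[1])
  expect_equal(de$direction[1], "down")
  # site 2: coverage 9 in both conditions -> excluded
  expect_false(de$significant[2])
  # site 3: delta 0.05 -> excluded
  expect_false(de$significant[3])
})

test_that("type I classification uses a strict 40% threshold", {
  counts <- data.frame(
    chrom = "chr1", pos = 1:3, gene_strand = "+",
    edited_ctrl = c(5L, 4L, 0L), unedited_ctrl = c(5L, 6L, 10L),
    edited_kd = 0L, unedited_kd = 0L, spliced_out = 0L)
  t1 <- classify_type1(counts)
  expect_equal(t1$type1_ctrl, c(TRUE, FALSE, FALSE))  # 50%, 40%, 0%
  expect_true(all(t1$type1_zero_cov))                 # kd has no coverage
})

test_that("type II regions match the spec examples", {
  r1 <- type2_regions(data.frame(chrom = "c", pos = c(1000L, 1050L, 1140L)))
  expect_equal(nrow(r1), 1)
  expect_equal(r1$n_edits, 3L)
  expect_equal(c(r1$start, r1$end), c(1000L, 1140L))
  r2 <- type2_regions(data.frame(chrom = "c", pos = c(1000L, 1200L, 1400L)))
  expect_equal(nrow(r2), 0)
  p3 <- c(1000L, 1050L, 1140L, 1260L, 1280L, 1300L)
  r3 <- type2_regions(data.frame(chrom = "c", pos = p3))
  want <- type2_oracle(p3)
  expect_equal(nrow(r3), nrow(want))
  expect_equal(r3$start, unname(want[, "start"]))
  expect_equal(r3$end, unname(want[, "end"]))
  expect_equal(r3$n_edits, unname(want[, "n"]))
})

test_that("type II detection equals the all-window oracle on random site
           sets", {
  set.seed(77)
  for (i in 1:50) {
    pos <- sort(sample(0:4000, sample(3:40, 1)))
    got <- type2_regions(data.frame(chrom = "c", pos = pos))
    want <- type2_oracle(pos)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start, unname(want[, "start"]))
      expect_equal(got$end, unname(want[, "end"]))
      expect_equal(got$n_edits, unname(want[, "n"]))
    }
  }
})

test_that("coordination pairs respect the distance rule and detect strong
           co-editing", {
  sites <- data.frame(chrom = "chr1", pos = c(100L, 140L, 300L), ref = "A",
                      alt = "G", gene_strand = "+", edited_base = "G")
  # 20 reads: 10 edited at both 100 and 300, 10 at neither
  prof <- matrix(NA_character_, 20, 3,
                 dimnames = list(paste0("r", 1:20), NULL))
  prof[1:10, c(1, 3)] <- "edited"
  prof[11:20, c(1, 3)] <- "unedited"
  prof[, 2] <- "unedited"
  res <- coordination_test(prof, sites)
  # the 40 bp pair (100,140) is excluded
  expect_false(any(res$pos1 == 100 & res$pos2 == 140))
  hit <- res[res$pos1 == 100 & res$pos2 == 300, ]
  expect_equal(hit$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(hit$coordinated)
})

test_that("pairs with no doubly-covered read are skipped and counted", {
  sites <- data.frame(chrom = "chr1", pos = c(100L, 300L), ref = "A",
                      alt = "G", gene_strand = "+", edited_base = "G")
  prof <- matrix(c("edited", NA, NA, "edited"), 2, 2)
  res <- coordination_test(prof, sites)
  expect_equal(nrow(res), 0)
  expect_equal(attr(res, "n_skipped"), 1)
})

test_that("under independent editing the coordination false-positive rate
           is near alpha", {
  set.seed(2024)
  n_reads <- 1000
  trials <- 400
  hits <- 0
  for (t in seq_len(trials)) {
    e1 <- stats::rbinom(n_reads, 1, 0.5)
    e2 <- stats::rbinom(n_reads, 1, 0.5)
    p <- fisher2x2(sum(e1 & e2), sum(e1 & !e2), sum(!e1 & e2),
                   sum(!e1 & !e2))$p
    hits <- hits + (p < 0.05)
  }
  expect_lt(abs(hits / trials - 0.05), 0.035)
})

test_that("edit/splice exclusivity keeps type-I sites with enough edited
           and spliced reads", {
  counts <- data.frame(
    chrom = "chr1", pos = 1:3, gene_strand = "+",
    edited_ctrl = c(12L, 12L, 6L), unedited_ctrl = c(15L, 15L, 14L),
    edited_kd = c(1L, 1L, 1L), unedited_kd = c(9L, 9L, 9L),
    spliced_out = c(11L, 9L, 11L))
  tab <- intron_editing(counts)
  # 44% edited, 12 edited, 11 spliced -> kept; 9 spliced -> dropped;
  # 30% edited -> fails type I
  expect_equal(tab$pos, 1L)
  expect_equal(tab[1, c("unedited", "edited", "spliced_out")],
               data.frame(unedited = 15L, edited = 12L, spliced_out = 11L),
               ignore_attr = TRUE)
})

test_that("the simulated knockdown pipeline recovers planted sites with
           spliced-out support at intronic sites", {
  cfg <- sim_config(seed = 9, n_genes = 3, isoforms_per_gene = 1,
                    coverage_per_haplotype = 25)
  ee <- simulate_editing_experiment(cfg, n_sites = 8, n_intronic = 2)
  cand <- candidate_inosines(ee$variants, ee$txome$models)
  expect_equal(nrow(cand), 8)           # all planted sites are candidates
  counts <- pileup_counts(ee$alns, cand)
  # intronic sites see spliced reads from the non-retaining isoform
  ir_pos <- setdiff(ee$sites$pos, counts$pos[counts$spliced_out == 0])
  expect_length(ir_pos, 2)
  de <- differential_editing(counts)
  expect_true(all(de$direction[de$significant] == "down"))
  expect_gt(sum(de$significant), 0)
})
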