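#' Simulation configuration
#'
#' Central knobs for the synthetic transcriptome and read generator. The
#' defaults describe the regime the package's haplotype calling is designed
#' for: consensus-style long reads at 99% per-base accuracy with tens of
#' reads per haplotype.
#'
#' @param seed Integer seed; every simulation routine derives its RNG stream
#'   from it, so equal seeds give byte-identical outputs.
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Isoforms per gene (>= 1; isoforms beyond the
#'   first are derived by exon skipping or alternative splice sites).
#' @param exon_count_range,exon_len_range,intron_len_range Integer length-2
#'   ranges.
#' @param per_base_accuracy Per-base accuracy of simulated reads in
#'   (0.5, 1]; errors are i.i.d. with substitution:insertion:deletion drawn
#'   50:25:25.
#' @param coverage_per_haplotype Reads per isoform per haplotype (>= 1).
#' @param truncation `list(model = "none")` for full-length reads or
#'   `list(model = "3prime_geometric", p = ...)` for 3'-anchored reads whose
#'   5' loss is geometric with parameter `p`.
#' @param gene_gap Intergenic spacer length in bp.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 5L, isoforms_per_gene = 2L,
                       exon_count_range = c(3L, 6L),
                       exon_len_range = c(80L, 300L),
                       intron_len_range = c(60L, 400L),
                       per_base_accuracy = 0.99,
                       coverage_per_haplotype = 20L,
                       truncation = list(model = "none", p = 0.01),
                       gene_gap = 500L) {
  stopifnot(per_base_accuracy > 0.5, per_base_accuracy <= 1,
            coverage_per_haplotype >= 1, n_genes >= 1,
            isoforms_per_gene >= 1, exon_count_range[1] >= 1,
            exon_len_range[1] >= 20, intron_len_range[1] >= 20,
            truncation$model %in% c("none", "3prime_geometric"))
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 isoforms_per_gene = as.integer(isoforms_per_gene),
                 exon_count_range = as.integer(exon_count_range),
                 exon_len_range = as.integer(exon_len_range),
                 intron_len_range = as.integer(intron_len_range),
                 per_base_accuracy = per_base_accuracy,
                 coverage_per_haplotype = as.integer(coverage_per_haplotype),
                 truncation = truncation, gene_gap = as.integer(gene_gap)),
            class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#' @param path YAML file whose keys mirror the [sim_config()] arguments.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

.DNA <- c("A", "C", "G", "T")

#' Synthetic transcriptome
#'
#' Builds a random genome with embedded multi-isoform genes. Genes alternate
#' strand; isoform 1 uses all exons, further isoforms skip an internal exon
#' or move a donor/acceptor (all junction chains distinct). Canonical splice
#' motifs (GT..AG in transcription direction) are planted at the gaps of the
#' full isoform so that strand is recoverable from sequence.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` (named [Biostrings::DNAStringSet], one
#'   chromosome `chr1`), `models` (named list of [transcript_model()]) and
#'   `truth` (`data.frame`: transcript_id, gene_id, strand, junction chain).
#' @export
make_transcriptome <- function(cfg) {
  set.seed(.subseed(cfg$seed, 1L))
  rint <- function(rng) sample(rng[1]:rng[2], 1)
  chrom_chars <- character(0)
  cursor <- 0L
  models <- list()
  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("g%02d", g)
    strand <- if (g %% 2 == 1) "+" else "-"
    n_ex <- rint(cfg$exon_count_range)
    ex_len <- vapply(seq_len(n_ex), function(i) rint(cfg$exon_len_range), 0L)
    in_len <- if (n_ex > 1)
      vapply(seq_len(n_ex - 1), function(i) rint(cfg$intron_len_range), 0L)
    else integer(0)
    glen <- sum(ex_len) + sum(in_len)
    gseq <- sample(.DNA, glen, replace = TRUE)
    starts <- cursor + c(0L, cumsum(ex_len + c(in_len, 0L))[-n_ex])
    ends <- starts + ex_len
    # plant canonical splice motifs in transcription direction
    for (k in seq_len(n_ex - 1)) {
      d <- ends[k] - cursor          # local 0-based intron start
      a <- starts[k + 1] - cursor    # local intron end
      if (strand == "+") {
        gseq[c(d + 1, d + 2)] <- c("G", "T")
        gseq[c(a - 1, a)] <- c("A", "G")
      } else {                       # reverse-complement of GT..AG
        gseq[c(d + 1, d + 2)] <- c("C", "T")
        gseq[c(a - 1, a)] <- c("A", "C")
      }
    }
    chrom_chars <- c(chrom_chars, gseq, sample(.DNA, cfg$gene_gap, TRUE))

    exall <- cbind(starts, ends)
    chains <- character(0)
    for (k in seq_len(cfg$isoforms_per_gene)) {
      tid <- sprintf("%stx%02d", gid, k)
      ex <- exall
      if (k > 1) {
        for (try in 1:25) {
          mode <- sample(c("skip", "donor", "acceptor"), 1)
          ex2 <- exall
          if (mode == "skip" && n_ex >= 3) {
            ex2 <- exall[-sample(2:(n_ex - 1), 1), , drop = FALSE]
          } else if (n_ex >= 2) {
            e <- sample(seq_len(n_ex - 1), 1)   # exon whose donor moves
            delta <- sample(6:30, 1)
            if (mode == "donor" && exall[e, 2] - exall[e, 1] > delta + 20)
              ex2[e, 2] <- ex2[e, 2] - delta
            if (mode == "acceptor" &&
                exall[e + 1, 2] - exall[e + 1, 1] > delta + 20)
              ex2[e + 1, 1] <- ex2[e + 1, 1] + delta
          }
          m2 <- transcript_model(tid, gid, "chr1", strand, ex2)
          if (!junction_chain(m2) %in% chains && nrow(ex2) >= 2) {
            ex <- ex2; break
          }
        }
      }
      m <- transcript_model(tid, gid, "chr1", strand, ex)
      if (junction_chain(m) %in% chains) next   # could not diversify
      chains <- c(chains, junction_chain(m))
      models[[tid]] <- m
    }
    cursor <- cursor + glen + cfg$gene_gap
  }
  genome <- Biostrings::DNAStringSet(setNames(paste(chrom_chars,
                                                    collapse = ""), "chr1"))
  truth <- data.frame(
    transcript_id = vapply(models, `[[`, "", "transcript_id"),
    gene_id = vapply(models, `[[`, "", "gene_id"),
    strand = vapply(models, `[[`, "", "strand"),
    chain = vapply(models, junction_chain, ""),
    stringsAsFactors = FALSE, row.names = NULL)
  list(genome = genome, models = models, truth = truth, cfg = cfg)
}

#' Plant SNVs in exons of a synthetic transcriptome
#'
#' Samples variant positions from the exon union of the requested genes with
#' a minimum spacing; reference alleles are read from the genome, alternate
#' alleles drawn uniformly from the other three bases.
#'
#' @param txome From [make_transcriptome()].
#' @param n Number of variants.
#' @param genes Gene ids to restrict to (default: all).
#' @param min_spacing Minimum distance between variants in bp (default 5).
#' @param seed Integer seed.
#' @return Variant `data.frame` (chrom, pos, ref, alt, phase_set = NA).
#' @export
plant_variants <- function(txome, n, genes = NULL, min_spacing = 5L,
                           seed = txome$cfg$seed) {
  set.seed(.subseed(seed, 2L))
  models <- txome$models
  if (!is.null(genes))
    models <- models[vapply(models, `[[`, "", "gene_id") %in% genes]
  pos_pool <- sort(unique(unlist(lapply(models, function(m)
    unlist(lapply(seq_len(nrow(m$exons)), function(i)
      seq(m$exons[i, 1], m$exons[i, 2] - 1L)))))))
  chosen <- integer(0)
  pool <- pos_pool
  while (length(chosen) < n && length(pool) > 0) {
    p <- sample(pool, 1)
    chosen <- c(chosen, p)
    pool <- pool[abs(pool - p) >= min_spacing]
  }
  if (length(chosen) < n) stop("could not place ", n, " variants")
  chosen <- sort(chosen)
  chrseq <- as.character(txome$genome[["chr1"]])
  ref <- vapply(chosen, function(p) substr(chrseq, p + 1, p + 1), "")
  alt <- vapply(ref, function(r) sample(setdiff(.DNA, r), 1), "")
  data.frame(chrom = "chr1", pos = chosen, ref = ref, alt = unname(alt),
             phase_set = NA_character_, stringsAsFactors = FALSE)
}

#' Simulate one read from a (possibly modified) transcript sequence
#'
#' `ref_b`/`mod_b` are aligned character vectors over the covered transcript
#' window; planted differences (variants, edits) become mismatches, and
#' i.i.d. sequencing errors (sub:ins:del = 50:25:25) are layered on top.
#' Returns the read sequence plus its true transcript-space op list.
#' @noRd
.sim_read_core <- function(ref_b, mod_b, err) {
  len <- length(mod_b)
  u <- stats::runif(len)
  kind <- ifelse(u < err * 0.5, 1L,
                 ifelse(u < err * 0.75, 2L, ifelse(u < err, 3L, 0L)))
  b <- mod_b
  for (i in which(kind == 1L)) b[i] <- sample(setdiff(.DNA, b[i]), 1)
  keep <- kind != 3L
  type <- ifelse(!keep, "deletion", ifelse(b == ref_b, "match", "mismatch"))
  ins_after <- which(kind == 2L)
  ins_base <- if (length(ins_after)) sample(.DNA, length(ins_after), TRUE)
  else character(0)
  # interleave insertion events after their anchor base
  ev_pos <- c(seq_len(len), ins_after)
  ev_sub <- c(rep(0L, len), rep(1L, length(ins_after)))
  ord <- order(ev_pos, ev_sub)
  ev <- c(type, rep("insertion", length(ins_after)))[ord]
  r <- rle(ev)
  ops <- data.frame(op = r$values, len = r$lengths, stringsAsFactors = FALSE)
  # read sequence in the same interleaved order
  rd_pos <- c(seq_len(len)[keep], ins_after)
  rd_sub <- c(rep(0L, sum(keep)), rep(1L, length(ins_after)))
  rd <- c(b[keep], ins_base)[order(rd_pos, rd_sub)]
  list(ops = ops, seq = paste(rd, collapse = ""),
       n_sub = sum(kind == 1L), n_ins = length(ins_after),
       n_del = sum(kind == 3L))
}

#' Lift a transcript-space alignment to genome space
#'
#' Splits ref-consuming ops at exon boundaries, inserting intron operations;
#' minus-strand models flip orientation (the stored sequence follows the SAM
#' convention: genome-forward).
#' @noRd
.lift_to_genome <- function(t_ops, t_start, read_seq, model, read_id,
                            mapq = 60L, tags = list()) {
  L <- tx_length(model)
  ops <- t_ops
  seq_fwd <- read_seq
  if (model$strand == "-") {
    ref_len <- sum(ops$len[.OP_REF[ops$op]])
    ops <- ops[rev(seq_len(nrow(ops))), , drop = FALSE]
    t_start <- L - (t_start + ref_len)
    seq_fwd <- .revcomp(read_seq)
  }
  ex <- model$exons
  lens <- ex[, 2] - ex[, 1]
  cum <- c(0L, cumsum(lens))
  # exon index and genomic coordinate of plus-layout offset pt
  locate <- function(pt) {
    i <- findInterval(pt, cum, rightmost.closed = FALSE)
    i <- min(i, nrow(ex))
    c(i, ex[i, 1] + (pt - cum[i]))
  }
  st <- locate(t_start)
  i_ex <- st[1]
  g <- st[2]
  g_start <- g
  out <- list()
  pend_intron <- 0L
  emit <- function(op, len) {
    if (pend_intron > 0L) {
      out[[length(out) + 1L]] <<- c("intron", pend_intron)
      pend_intron <<- 0L
    }
    out[[length(out) + 1L]] <<- c(op, len)
  }
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; l <- ops$len[k]
    if (!.OP_REF[[op]]) { emit(op, l); next }
    while (l > 0L) {
      room <- ex[i_ex, 2] - g
      if (room == 0L) {
        pend_intron <- pend_intron + (ex[i_ex + 1L, 1] - ex[i_ex, 2])
        i_ex <- i_ex + 1L
        g <- ex[i_ex, 1]
        next
      }
      take <- min(room, l)
      emit(op, take)
      g <- g + take
      l <- l - take
    }
  }
  om <- do.call(rbind, out)
  odf <- data.frame(op = om[, 1], len = as.integer(om[, 2]),
                    stringsAsFactors = FALSE)
  # merge adjacent identical ops (splits at exon boundaries may rejoin)
  if (nrow(odf) > 1) {
    keepi <- c(TRUE, odf$op[-1] != odf$op[-nrow(odf)])
    grp <- cumsum(keepi)
    odf <- data.frame(op = odf$op[keepi],
                      len = as.integer(tapply(odf$len, grp, sum)),
                      stringsAsFactors = FALSE)
  }
  read_alignment(read_id, model$chrom, "genome", target_start = g_start,
                 ops = odf, mapq = mapq, seq = seq_fwd,
                 strand = model$strand, tags = tags)
}

#' Simulate long reads from a transcriptome with haplotypes
#'
#' Draws `coverage_per_haplotype` reads per isoform per haplotype. Haplotype
#' sequences substitute the alternate allele at each of their variant sites
#' (strand-aware); 3'-anchored truncation and i.i.d. sequencing errors are
#' applied per read. Each read is emitted with its ground-truth alignment to
#' its transcript and to the genome, so downstream modules run without an
#' external aligner.
#'
#' @param txome From [make_transcriptome()].
#' @param variants Variant `data.frame` (needed when `haplotypes` given).
#' @param haplotypes Named list: haplotype name -> character vector of
#'   variant keys (`"chrom:pos"`) carrying the alternate allele (all other
#'   planted sites are reference). `NULL` simulates unphased reference reads
#'   (one haplotype named `"ref"`).
#' @param cfg A [sim_config()] (defaults to the transcriptome's).
#' @param tag_phase_sets When TRUE, genomic alignments carry `PS` (gene id)
#'   and `HP` (haplotype index) tags, emulating a phasing caller's output.
#' @return List with `reads` (named [Biostrings::DNAStringSet]), `truth`
#'   (`data.frame`: read_id, transcript_id, haplotype, error counts),
#'   `tx_alns` and `genomic_alns` (named lists of [read_alignment()]).
#' @export
simulate_reads <- function(txome, variants = NULL, haplotypes = NULL,
                           cfg = txome$cfg, tag_phase_sets = FALSE) {
  set.seed(.subseed(cfg$seed, 3L))
  if (is.null(haplotypes)) haplotypes <- list(ref = character(0))
  err <- 1 - cfg$per_base_accuracy
  vkey <- if (is.null(variants)) character(0) else
    paste0(variants$chrom, ":", variants$pos)

  reads <- character(0)
  tx_alns <- list()
  g_alns <- list()
  truth <- list()
  ref_seqs <- transcript_sequences(txome$models, txome$genome)
  for (m in txome$models) {
    L <- tx_length(m)
    ref_b <- strsplit(as.character(ref_seqs[[m$transcript_id]]), "")[[1]]
    # transcript offsets + alt bases of planted variants inside this model
    t_off <- if (length(vkey)) genome_to_tx(m, variants$pos) else integer(0)
    inside <- which(!is.na(t_off))
    for (h in seq_along(haplotypes)) {
      hname <- names(haplotypes)[h]
      hap_b <- ref_b
      for (vi in inside) {
        if (!vkey[vi] %in% haplotypes[[h]]) next
        ab <- if (m$strand == "-") .comp_base(variants$alt[vi]) else
          variants$alt[vi]
        hap_b[t_off[vi] + 1L] <- ab
      }
      for (r in seq_len(cfg$coverage_per_haplotype)) {
        rid <- sprintf("%s.%s.%03d", m$transcript_id, hname, r)
        t0 <- 0L
        if (cfg$truncation$model == "3prime_geometric") {
          loss <- min(stats::rgeom(1, cfg$truncation$p), L - 50L)
          t0 <- as.integer(loss)
        }
        sim <- .sim_read_core(ref_b[(t0 + 1L):L], hap_b[(t0 + 1L):L], err)
        tags <- if (tag_phase_sets)
          list(HP = h, PS = m$gene_id) else list()
        tx_alns[[rid]] <- read_alignment(rid, m$transcript_id, "transcript",
                                         target_start = t0, ops = sim$ops,
                                         seq = sim$seq)
        g_alns[[rid]] <- .lift_to_genome(sim$ops, t0, sim$seq, m, rid,
                                         tags = tags)
        reads[rid] <- sim$seq
        truth[[rid]] <- data.frame(read_id = rid,
                                   transcript_id = m$transcript_id,
                                   haplotype = hname, t_start = t0,
                                   n_sub = sim$n_sub, n_ins = sim$n_ins,
                                   n_del = sim$n_del,
                                   stringsAsFactors = FALSE)
      }
    }
  }
  list(reads = Biostrings::DNAStringSet(reads),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       tx_alns = tx_alns, genomic_alns = g_alns)
}

#' Write simulated reads as FASTQ
#' @param reads Named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @param quality Constant Phred quality character (default `"I"`, Q40).
#' @export
write_fastq <- function(reads, path, quality = "I") {
  q <- Biostrings::BStringSet(vapply(Biostrings::width(reads),
                                     function(w) strrep(quality, w), ""))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Add an intron-retention isoform per gene
#'
#' For each gene's full-length isoform, adds a second model retaining one
#' intron (two exons merged), so that positions inside that intron are
#' exonic for the new isoform but spliced out by the others.
#'
#' @param txome From [make_transcriptome()].
#' @param which_intron Index of the retained intron (default 1).
#' @return The transcriptome with `<gene>txIR` models appended.
#' @export
add_intron_retention <- function(txome, which_intron = 1L) {
  for (gid in unique(vapply(txome$models, `[[`, "", "gene_id"))) {
    base <- NULL
    for (m in txome$models)
      if (m$gene_id == gid && is.null(base)) base <- m
    if (nrow(base$exons) < 2) next
    k <- min(which_intron, nrow(base$exons) - 1L)
    ex <- base$exons
    ex[k, 2] <- ex[k + 1L, 2]
    ex <- ex[-(k + 1L), , drop = FALSE]
    tid <- paste0(gid, "txIR")
    txome$models[[tid]] <- transcript_model(tid, gid, base$chrom,
                                            base$strand, ex)
  }
  txome
}

#' Simulate a two-condition editing experiment
#'
#' Generates control and ADAR-knockdown read sets over a transcriptome in
#' which each read is independently edited at each exonic site with its
#' condition's fraction. Edited positions carry the transcribed-strand A>G
#' change (genomic T>C on minus-strand genes). When the transcriptome
#' includes intron-retention isoforms, sites inside retained introns are
#' edited only on reads of the retaining isoform and appear spliced-out on
#' the others.
#'
#' @param cfg A [sim_config()].
#' @param txome Optional transcriptome; by default one is built from `cfg`
#'   and an intron-retention isoform is added per gene.
#' @param edit_sites Optional `data.frame` with `chrom`, `pos`,
#'   `fraction_ctrl`, `fraction_kd`; by default `n_sites` transcribed-A
#'   positions are sampled per the defaults below.
#' @param n_sites Number of auto-planted sites (default 10).
#' @param fraction_ctrl,fraction_kd Default edit fractions for auto-planted
#'   sites (default 0.6 and 0.2, an ADAR-knockdown-style drop).
#' @param n_intronic Of the auto-planted sites, how many to place inside the
#'   retained introns (default 2).
#' @param n_replicates Sequencing replicates per condition (default 1);
#'   replicates are pooled downstream by [pileup_counts()], mirroring the
#'   combined-replicate design of a knockdown experiment.
#' @return List with `alns` (list `ctrl`/`kd` of named read-alignment
#'   lists), `sites` (the planted `data.frame` with `gene_strand`),
#'   `variants` (caller-style SNV `data.frame` for
#'   [candidate_inosines()]) and `txome`.
#' @export
simulate_editing_experiment <- function(cfg, txome = NULL, edit_sites = NULL,
                                        n_sites = 10L, fraction_ctrl = 0.6,
                                        fraction_kd = 0.2, n_intronic = 2L,
                                        n_replicates = 1L) {
  if (is.null(txome)) txome <- add_intron_retention(make_transcriptome(cfg))
  set.seed(.subseed(cfg$seed, 4L))
  chrseq <- as.character(txome$genome[["chr1"]])
  base_at <- function(p) substr(chrseq, p + 1, p + 1)

  if (is.null(edit_sites)) {
    # exonic transcribed-A positions; prefer some inside retained introns
    cand <- list()
    for (m in txome$models) {
      want <- if (m$strand == "+") "A" else "T"
      for (i in seq_len(nrow(m$exons))) {
        pp <- seq(m$exons[i, 1], m$exons[i, 2] - 1L)
        pp <- pp[vapply(pp, base_at, "") == want]
        cand[[length(cand) + 1L]] <- data.frame(
          pos = pp, gene = m$gene_id, tid = m$transcript_id,
          strand = m$strand, stringsAsFactors = FALSE)
      }
    }
    cand <- do.call(rbind, cand)
    # positions exonic only in the IR isoform = retained-intron positions
    tab <- table(cand$pos)
    ir_only <- as.integer(names(tab)[tab == 1 &
      tapply(grepl("txIR$", cand$tid), cand$pos, all)])
    shared <- setdiff(unique(cand$pos), ir_only)
    n_ir <- min(n_intronic, length(ir_only))
    pos <- c(if (n_ir > 0) sort(sample(ir_only, n_ir)),
             sort(sample(shared, n_sites - n_ir)))
    edit_sites <- data.frame(chrom = "chr1", pos = sort(pos),
                             fraction_ctrl = fraction_ctrl,
                             fraction_kd = fraction_kd,
                             stringsAsFactors = FALSE)
  }
  edit_sites$gene_strand <- vapply(edit_sites$pos, function(p) {
    for (m in txome$models)
      if (p >= m$exons[1, 1] && p < m$exons[nrow(m$exons), 2])
        return(m$strand)
    NA_character_
  }, "")

  err <- 1 - cfg$per_base_accuracy
  ref_seqs <- transcript_sequences(txome$models, txome$genome)
  out <- list(ctrl = list(), kd = list())
  for (cond in c("ctrl", "kd")) {
    fcol <- paste0("fraction_", cond)
    for (m in txome$models) {
      ref_b <- strsplit(as.character(ref_seqs[[m$transcript_id]]), "")[[1]]
      t_off <- genome_to_tx(m, edit_sites$pos)
      inside <- which(!is.na(t_off))
      for (rep in seq_len(n_replicates))
      for (r in seq_len(cfg$coverage_per_haplotype)) {
        rid <- sprintf("%s.%s%d.%03d", m$transcript_id, cond, rep, r)
        mod_b <- ref_b
        for (vi in inside) {
          # transcribed-strand base is A at a planted site; editing makes G
          if (stats::runif(1) < edit_sites[[fcol]][vi])
            mod_b[t_off[vi] + 1L] <- "G"
        }
        sim <- .sim_read_core(ref_b, mod_b, err)
        out[[cond]][[rid]] <- .lift_to_genome(sim$ops, 0L, sim$seq, m, rid)
      }
    }
  }
  variants <- data.frame(
    chrom = edit_sites$chrom, pos = edit_sites$pos,
    ref = vapply(edit_sites$pos, base_at, ""),
    alt = ifelse(edit_sites$gene_strand == "-", "C", "G"),
    phase_set = NA_character_, stringsAsFactors = FALSE)
  list(alns = out, sites = edit_sites, variants = variants, txome = txome)
}
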