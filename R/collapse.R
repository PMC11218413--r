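#' Splice-junction evidence set
#'
#' Collects trusted splice boundaries from annotation and (optionally)
#' short-read junction calls; used to correct noisy long-read junctions.
#'
#' @param models Optional list of [transcript_model()] (annotation evidence).
#' @param junction_bed Optional `data.frame` with columns `chrom`, `start`,
#'   `end` (0-based half-open intron coordinates) and optionally `strand`,
#'   `score` (short-read evidence, BED-style).
#' @return An object of class `junction_evidence`: a `data.frame` with
#'   columns `chrom`, `donor_end`, `acceptor_start`, `strand`, `weight`.
#' @export
junction_evidence <- function(models = NULL, junction_bed = NULL) {
  rows <- list()
  for (m in models) {
    j <- tx_junctions(m)
    if (nrow(j) > 0)
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = m$chrom, donor_end = j[, 1],
                   acceptor_start = j[, 2], strand = m$strand, weight = 1,
                   stringsAsFactors = FALSE)
  }
  if (!is.null(junction_bed)) {
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = junction_bed$chrom, donor_end = junction_bed$start,
      acceptor_start = junction_bed$end,
      strand = if (is.null(junction_bed$strand)) "*" else junction_bed$strand,
      weight = if (is.null(junction_bed$score)) 1 else junction_bed$score,
      stringsAsFactors = FALSE)
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), donor_end = integer(),
               acceptor_start = integer(), strand = character(),
               weight = numeric())
  ev <- ev[!duplicated(ev[, c("chrom", "donor_end", "acceptor_start")]), ,
           drop = FALSE]
  stopifnot(all(ev$donor_end < ev$acceptor_start))
  class(ev) <- c("junction_evidence", "data.frame")
  ev
}

#' Snap one boundary to the evidence set
#'
#' Nearest evidence boundary within `window` bp; ties prefer the smaller
#' shift magnitude is equal on both sides, so then the leftmost coordinate.
#' @noRd
.snap_boundary <- function(x, set, window) {
  if (length(set) == 0) return(NA_integer_)
  if (x %in% set) return(x)
  d <- abs(set - x)
  ok <- d <= window
  if (!any(ok)) return(NA_integer_)
  cand <- set[ok][d[ok] == min(d[ok])]
  min(cand)
}

#' Correct a read's splice junctions against evidence
#'
#' Each junction boundary already present in the evidence set is kept;
#' otherwise it is snapped to the nearest evidence boundary within `window`
#' bp (ties: smaller shift, then leftmost). A junction with no evidence
#' boundary in range rejects the read for isoform building. The alignment is
#' rewritten so that a shifted boundary appears as a small insertion (read
#' bases displaced into the intron) or deletion (reference bases the read
#' skips) at the splice site; the read's bases themselves are unchanged.
#'
#' @param aln A genome-target [read_alignment()] (possibly unspliced).
#' @param evidence A [junction_evidence()] set.
#' @param window Maximum snap distance in bp (default 10).
#' @return The corrected [read_alignment()], or `NULL` when rejected.
#' @export
correct_junctions <- function(aln, evidence, window = 10L) {
  stopifnot(aln$target_kind == "genome")
  ev <- evidence[evidence$chrom == aln$target_id, , drop = FALSE]
  donors <- sort(unique(ev$donor_end))
  acceptors <- sort(unique(ev$acceptor_start))

  ops <- aln$ops
  intron_idx <- which(ops$op == "intron")
  if (length(intron_idx) == 0) return(aln)

  # genomic start of each op
  r <- aln$target_start
  op_start <- integer(nrow(ops))
  for (i in seq_len(nrow(ops))) {
    op_start[i] <- r
    if (.OP_REF[ops$op[i]]) r <- r + ops$len[i]
  }

  segs <- split(seq_len(nrow(ops)),
                cumsum(ops$op == "intron") - (ops$op == "intron"))
  # segs: alternating exon-block op indices keyed by number of introns before
  blocks <- lapply(segs, function(ix) ops[ix[ops$op[ix] != "intron"], ,
                                          drop = FALSE])
  n_introns <- length(intron_idx)
  stopifnot(length(blocks) == n_introns + 1L)

  for (k in seq_len(n_introns)) {
    i <- intron_idx[k]
    d <- op_start[i]
    a <- d + ops$len[i]
    d2 <- .snap_boundary(d, donors, window)
    a2 <- .snap_boundary(a, acceptors, window)
    if (is.na(d2) || is.na(a2) || d2 >= a2) return(NULL)

    blk <- blocks[[k]]
    dd <- d2 - d   # donor shift
    if (dd > 0) {
      blk <- rbind(blk, data.frame(op = "deletion", len = dd))
    } else if (dd < 0) {
      res <- .trim_ops_tail(blk, -dd)
      if (is.null(res)) return(NULL)
      blk <- res$ops
      if (res$read_bases > 0)
        blk <- rbind(blk, data.frame(op = "insertion", len = res$read_bases))
    }
    blocks[[k]] <- blk

    nxt <- blocks[[k + 1L]]
    aa <- a2 - a   # acceptor shift
    if (aa < 0) {
      nxt <- rbind(data.frame(op = "deletion", len = -aa), nxt)
    } else if (aa > 0) {
      res <- .trim_ops_head(nxt, aa)
      if (is.null(res)) return(NULL)
      nxt <- res$ops
      if (res$read_bases > 0)
        nxt <- rbind(data.frame(op = "insertion", len = res$read_bases), nxt)
    }
    blocks[[k + 1L]] <- nxt
    intron_len <- a2 - d2
    blocks[[k]] <- rbind(blocks[[k]],
                         data.frame(op = "intron", len = intron_len))
  }

  allops <- do.call(rbind, blocks)
  allops <- allops[allops$len > 0, , drop = FALSE]
  # merge adjacent identical ops
  if (nrow(allops) > 1) {
    keep <- c(TRUE, allops$op[-1] != allops$op[-nrow(allops)])
    grp <- cumsum(keep)
    allops <- data.frame(op = allops$op[keep],
                         len = as.integer(tapply(allops$len, grp, sum)),
                         stringsAsFactors = FALSE)
  }
  # first junction's donor shift moves target_start only if the first block
  # was fully consumed (degenerate); start is otherwise unchanged
  read_alignment(aln$read_id, aln$target_id, "genome",
                 target_start = aln$target_start, ops = allops,
                 mapq = aln$mapq, seq = aln$seq, strand = aln$strand,
                 tags = aln$tags)
}

#' Trim `n` reference bases off the tail of an exon-block op list; returns the
#' trimmed ops and how many read bases were displaced (become an insertion).
#' @noRd
.trim_ops_tail <- function(ops, n) {
  read_bases <- 0L
  while (n > 0) {
    if (nrow(ops) == 0) return(NULL)
    i <- nrow(ops)
    op <- ops$op[i]
    if (!.OP_REF[[op]]) {            # trailing insertion: displaced wholesale
      read_bases <- read_bases + ops$len[i]
      ops <- ops[-i, , drop = FALSE]
      next
    }
    take <- min(n, ops$len[i])
    if (.OP_READ[[op]]) read_bases <- read_bases + take
    ops$len[i] <- ops$len[i] - take
    n <- n - take
    if (ops$len[i] == 0) ops <- ops[-i, , drop = FALSE]
  }
  list(ops = ops, read_bases = read_bases)
}

#' @noRd
.trim_ops_head <- function(ops, n) {
  read_bases <- 0L
  while (n > 0) {
    if (nrow(ops) == 0) return(NULL)
    op <- ops$op[1]
    if (!.OP_REF[[op]]) {
      read_bases <- read_bases + ops$len[1]
      ops <- ops[-1, , drop = FALSE]
      next
    }
    take <- min(n, ops$len[1])
    if (.OP_READ[[op]]) read_bases <- read_bases + take
    ops$len[1] <- ops$len[1] - take
    n <- n - take
    if (ops$len[1] == 0) ops <- ops[-1, , drop = FALSE]
  }
  list(ops = ops, read_bases = read_bases)
}

#' Group corrected reads by junction chain
#'
#' Spliced reads group by exact equality of their (chromosome, junction
#' chain); single-exon reads are clustered per locus by >= 50% reciprocal
#' overlap (single linkage).
#'
#' @param alns List of corrected genome-target [read_alignment()].
#' @return Named list of read-alignment lists; names are junction-chain keys
#'   (`"chr:d1-a1,..."`) or `"chr:single:<n>"` for single-exon clusters.
#' @export
group_by_junction_chain <- function(alns) {
  if (length(alns) == 0) return(list())
  keys <- character(length(alns))
  single <- logical(length(alns))
  for (i in seq_along(alns)) {
    j <- read_junctions(alns[[i]])
    if (nrow(j) == 0) {
      single[i] <- TRUE
    } else {
      keys[i] <- paste0(alns[[i]]$target_id, ":",
                        paste(paste0(j[, 1], "-", j[, 2]), collapse = ","))
    }
  }
  out <- split(alns[!single], keys[!single])

  # single-exon loci: single-linkage clusters under 50% reciprocal overlap
  sidx <- which(single)
  if (length(sidx) > 0) {
    sp <- data.frame(chrom = vapply(alns[sidx], `[[`, "", "target_id"),
                     start = vapply(alns[sidx], `[[`, 0L, "target_start"),
                     end = vapply(alns[sidx], function(a) aln_target_end(a),
                                  0))
    for (chrom in unique(sp$chrom)) {
      ci <- which(sp$chrom == chrom)
      comp <- seq_along(ci)                 # union-find by replacement
      for (x in seq_along(ci)) for (y in seq_len(x - 1L)) {
        o <- min(sp$end[ci[x]], sp$end[ci[y]]) -
          max(sp$start[ci[x]], sp$start[ci[y]])
        wx <- sp$end[ci[x]] - sp$start[ci[x]]
        wy <- sp$end[ci[y]] - sp$start[ci[y]]
        if (o >= 0.5 * wx && o >= 0.5 * wy)
          comp[comp == comp[x]] <- comp[y]
      }
      for (cl in unique(comp)) {
        members <- sidx[ci[comp == cl]]
        out[[paste0(chrom, ":single:", cl)]] <- alns[members]
      }
    }
  }
  out
}

#' First-pass isoform
#' @noRd
.first_pass <- function(chrom, junctions, tss, tes, read_ids, strands) {
  structure(list(chrom = chrom, junctions = junctions, tss = tss, tes = tes,
                 read_ids = read_ids, strands = strands),
            class = "first_pass_isoform")
}

#' 1-d single-linkage clustering: split sorted positions where the gap
#' between consecutive values exceeds `window`.
#' @noRd
.cluster_positions <- function(x, window) {
  ord <- order(x)
  xs <- x[ord]
  brk <- c(0L, which(diff(xs) > window), length(xs))
  cl <- integer(length(x))
  for (k in seq_len(length(brk) - 1L))
    cl[ord[(brk[k] + 1L):brk[k + 1L]]] <- k
  cl
}

#' Call transcription start/end sites for one junction-chain group
#'
#' Read 5' start and 3' end positions are clustered with single linkage at
#' `end_window` bp; each cluster is represented by its most frequent position
#' (ties: smallest coordinate). At most `max_per_chain` TSS clusters and as
#' many TES clusters are retained, by descending read count. An isoform is
#' emitted for each (TSS, TES) pairing supported by at least one read whose
#' start and end fall in both clusters.
#'
#' @param group List of [read_alignment()] sharing one junction chain.
#' @param max_per_chain Maximum TSS (and TES) clusters kept (default 2).
#' @param end_window Fuzzy end window in bp (default 100).
#' @return List of `first_pass_isoform` objects.
#' @export
call_ends <- function(group, max_per_chain = 2L, end_window = 100L) {
  stopifnot(length(group) > 0)
  starts <- vapply(group, `[[`, 0L, "target_start")
  ends <- vapply(group, function(a) as.integer(aln_target_end(a)), 0L)
  jx <- read_junctions(group[[1]])
  chrom <- group[[1]]$target_id

  pick <- function(pos) {
    cl <- .cluster_positions(pos, end_window)
    sizes <- table(cl)
    # deterministic: among equally sized clusters prefer smaller representative
    reps <- vapply(unique(cl), function(k) {
      tt <- table(pos[cl == k])
      as.integer(names(tt)[tt == max(tt)][1])
    }, 0L)
    names(reps) <- unique(cl)
    ordk <- order(-as.integer(sizes[as.character(unique(cl))]),
                  reps[as.character(unique(cl))])
    kept <- unique(cl)[ordk][seq_len(min(max_per_chain, length(ordk)))]
    list(cluster = cl, kept = kept, reps = reps)
  }
  ps <- pick(starts)
  pe <- pick(ends)

  out <- list()
  for (ks in ps$kept) for (ke in pe$kept) {
    sel <- ps$cluster == ks & pe$cluster == ke
    if (!any(sel)) next
    tss <- ps$reps[[as.character(ks)]]
    tes <- pe$reps[[as.character(ke)]]
    if (nrow(jx) > 0 && (tss >= jx[1, 1] || tes <= jx[nrow(jx), 2])) next
    out[[length(out) + 1L]] <- .first_pass(
      chrom, jx, tss, tes,
      read_ids = vapply(group[sel], `[[`, "", "read_id"),
      strands = vapply(group[sel], `[[`, "", "strand"))
  }
  out
}

#' Build a transcript model from a first-pass isoform
#' @noRd
.fp_model <- function(fp, id, gene_id, strand) {
  j <- fp$junctions
  if (nrow(j) == 0) {
    exons <- cbind(fp$tss, fp$tes)
  } else {
    exons <- cbind(c(fp$tss, j[, 2]), c(j[, 1], fp$tes))
  }
  transcript_model(id, gene_id, fp$chrom, strand, exons)
}

#' Infer strand of a first-pass isoform
#'
#' Splice-site dinucleotides (GT..AG forward, CT..AC reverse) when a genome
#' is available; falls back to the majority strand of the supporting reads.
#' @noRd
.fp_strand <- function(fp, genome) {
  if (!is.null(genome) && nrow(fp$junctions) > 0 &&
      fp$chrom %in% names(genome)) {
    chr <- genome[[fp$chrom]]
    fwd <- 0L; rev <- 0L
    for (r in seq_len(nrow(fp$junctions))) {
      d <- fp$junctions[r, 1]; a <- fp$junctions[r, 2]
      don <- as.character(Biostrings::subseq(chr, d + 1L, d + 2L))
      acc <- as.character(Biostrings::subseq(chr, a - 1L, a))
      if (don == "GT" && acc == "AG") fwd <- fwd + 1L
      if (don == "CT" && acc == "AC") rev <- rev + 1L
    }
    if (fwd > rev) return("+")
    if (rev > fwd) return("-")
  }
  if (sum(fp$strands == "-") > sum(fp$strands == "+")) "-" else "+"
}

#' Finalise novel isoforms by realignment and support filtering
#'
#' Each unassigned read is realigned (projection through exon structure) to
#' every first-pass isoform and assigned with the same splice-fidelity rules
#' used for annotated transcripts; isoforms keeping at least `min_support`
#' reads survive. Isoform ids are `<chain-hash>_<gene-or-locus>`, stable
#' across runs.
#'
#' @param first_pass List of `first_pass_isoform` (from [call_ends()]).
#' @param alns List of genome-target [read_alignment()] (the unassigned
#'   reads, junction-corrected).
#' @param genome Optional named [Biostrings::DNAStringSet] (strand motifs).
#' @param annotation Optional list of [transcript_model()] used to label
#'   novel isoforms with a gene id by junction sharing.
#' @param min_support Minimum supporting reads (default 3).
#' @param ... Fidelity parameters passed to [assign_read()].
#' @return List with `models` (named list of [transcript_model()]) and
#'   `read_map` (named list isoform id -> read ids).
#' @export
finalize_isoforms <- function(first_pass, alns, genome = NULL,
                              annotation = NULL, min_support = 3L, ...) {
  if (length(first_pass) == 0)
    return(list(models = list(), read_map = list()))
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)

  ann_j <- list()
  for (m in annotation) {
    j <- tx_junctions(m)
    for (r in seq_len(nrow(j)))
      ann_j[[paste(m$chrom, j[r, 1], j[r, 2])]] <- m$gene_id
  }

  models <- list()
  for (fp in first_pass) {
    strand <- .fp_strand(fp, genome)
    gene <- NA_character_
    for (r in seq_len(nrow(fp$junctions))) {
      g <- ann_j[[paste(fp$chrom, fp$junctions[r, 1], fp$junctions[r, 2])]]
      if (!is.null(g)) { gene <- g; break }
    }
    if (is.na(gene)) gene <- paste0(fp$chrom, ".", fp$tss)
    chain <- paste0(fp$chrom, ":", fp$tss, ":",
                    paste(fp$junctions[, 1], fp$junctions[, 2],
                          collapse = ","), ":", fp$tes)
    id <- paste0(.fnv1a(chain), "_", gene)
    models[[id]] <- .fp_model(fp, id, gene, strand)
  }

  assignments <- assign_to_annotation(alns, models, ...)
  kept <- supported_annotated_isoforms(assignments, min_support = min_support)
  list(models = models[names(kept$supported)], read_map = kept$supported)
}

#' Full isoform detection from genomic read alignments
#'
#' The complete collapse flow: (1) annotation-reliant assignment of every
#' read to annotated transcripts under the stringent/splice-check rules;
#' (2) annotated isoforms with sufficient support are kept; (3) remaining
#' reads have their junctions corrected against annotation (plus optional
#' short-read junctions), are grouped by junction chain, ends are called, and
#' first-pass isoforms are built; (4) reads are realigned to the first-pass
#' set and novel isoforms passing the support threshold join the final set.
#'
#' @param alns List of genome-target [read_alignment()].
#' @param models Named list of annotated [transcript_model()].
#' @param genome Named [Biostrings::DNAStringSet] or FASTA path.
#' @param junction_bed Optional short-read junction `data.frame`
#'   (see [junction_evidence()]).
#' @param min_support Minimum supporting reads per isoform (default 3).
#' @param correction_window Junction snap window in bp (default 10).
#' @param end_window Fuzzy TSS/TES window in bp (default 100).
#' @param ... Fidelity parameters passed to [assign_read()].
#' @return List with `isoforms` (named list of [transcript_model()]: kept
#'   annotated + novel), `read_map`, `unassigned` (read ids supporting
#'   nothing) and `n_correct_rejected` (reads dropped at junction
#'   correction).
#' @export
detect_isoforms <- function(alns, models, genome, junction_bed = NULL,
                            min_support = 3L, correction_window = 10L,
                            end_window = 100L, ...) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  assignments <- assign_to_annotation(alns, models, ...)
  ann <- supported_annotated_isoforms(assignments, min_support = min_support)

  pool_ids <- ann$unassigned
  pool <- alns[vapply(alns, `[[`, "", "read_id") %in% pool_ids]
  ev <- junction_evidence(models, junction_bed)
  corrected <- list()
  n_rej <- 0L
  for (a in pool) {
    ca <- correct_junctions(a, ev, window = correction_window)
    if (is.null(ca)) n_rej <- n_rej + 1L
    else corrected[[length(corrected) + 1L]] <- ca
  }
  groups <- group_by_junction_chain(corrected)
  first_pass <- list()
  for (g in groups)
    first_pass <- c(first_pass, call_ends(g, end_window = end_window))
  novel <- finalize_isoforms(first_pass, corrected, genome = genome,
                             annotation = models, min_support = min_support,
                             ...)

  iso <- c(models[names(ann$supported)], novel$models)
  read_map <- c(ann$supported, novel$read_map)
  assigned <- unlist(read_map, use.names = FALSE)
  all_ids <- vapply(alns, `[[`, "", "read_id")
  list(isoforms = iso, read_map = read_map,
       unassigned = setdiff(all_ids, assigned),
       n_correct_rejected = n_rej)
}
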