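#' Read alignment as an explicit operation list
#'
#' One read's alignment to a target (a transcript sequence or the genome) as
#' an ordered list of operations with base-level accounting. Operations are
#' `match`, `mismatch`, `insertion`, `deletion` and (genome targets only)
#' `intron`. Coordinates are 0-based half-open on the target; for transcript
#' targets they are in transcript orientation. `seq`, when present, is the
#' aligned read sequence in target-forward orientation with soft-clipped
#' bases removed (SAM convention).
#'
#' @param read_id,target_id Character scalars.
#' @param target_kind `"transcript"` or `"genome"`.
#' @param target_start 0-based start on the target.
#' @param ops `data.frame` with columns `op` (character) and `len`
#'   (positive integer).
#' @param mapq Mapping quality (integer).
#' @param seq Optional aligned read sequence (character scalar).
#' @param strand Strand of the read on the target (`"+"`/`"-"`).
#' @param tags Optional named list of auxiliary tags (e.g. `HP`, `PS`).
#' @return An object of class `read_alignment`.
#' @export
read_alignment <- function(read_id, target_id,
                           target_kind = c("transcript", "genome"),
                           target_start, ops, mapq = 60L, seq = NULL,
                           strand = "+", tags = list()) {
  target_kind <- match.arg(target_kind)
  ops <- data.frame(op = as.character(ops$op), len = as.integer(ops$len),
                    stringsAsFactors = FALSE)
  valid <- c("match", "mismatch", "insertion", "deletion", "intron")
  stopifnot(all(ops$op %in% valid), all(ops$len > 0), target_start >= 0)
  if (target_kind == "transcript" && any(ops$op == "intron"))
    stop("intron operations are only valid for genome alignments")
  structure(list(read_id = read_id, target_id = target_id,
                 target_kind = target_kind,
                 target_start = as.integer(target_start), ops = ops,
                 mapq = as.integer(mapq), seq = seq, strand = strand,
                 tags = tags),
            class = "read_alignment")
}

#' @exportS3Method base::print
print.read_alignment <- function(x, ...) {
  cat(sprintf("<read_alignment> %s -> %s (%s%s) @%d  %s  mapq=%d\n",
              x$read_id, x$target_id, x$target_kind,
              if (x$strand == "-") ", -" else "",
              x$target_start, .ops_to_cigar(x$ops), x$mapq))
  invisible(x)
}

.OP_REF <- c(match = TRUE, mismatch = TRUE, insertion = FALSE,
             deletion = TRUE, intron = TRUE)
.OP_READ <- c(match = TRUE, mismatch = TRUE, insertion = TRUE,
              deletion = FALSE, intron = FALSE)
.OP_CIG <- c(match = "=", mismatch = "X", insertion = "I",
             deletion = "D", intron = "N")
.CIG_OP <- c("=" = "match", X = "mismatch", I = "insertion",
             D = "deletion", N = "intron", M = "match")

#' Target span end of an alignment
#' @param aln A [read_alignment()].
#' @return 0-based exclusive end coordinate on the target.
#' @export
aln_target_end <- function(aln) {
  aln$target_start + sum(aln$ops$len[.OP_REF[aln$ops$op]])
}

#' Number of aligned read bases (insertions included, clips excluded)
#' @param aln A [read_alignment()].
#' @export
aln_read_bases <- function(aln) sum(aln$ops$len[.OP_READ[aln$ops$op]])

#' Splice junctions observed in a genomic read alignment
#'
#' @param aln A genome-target [read_alignment()].
#' @return Integer matrix with columns `donor_end`, `acceptor_start`, one row
#'   per intron operation, in target order.
#' @export
read_junctions <- function(aln) {
  stopifnot(aln$target_kind == "genome")
  pos <- aln$target_start
  res <- NULL
  for (i in seq_len(nrow(aln$ops))) {
    op <- aln$ops$op[i]; len <- aln$ops$len[i]
    if (op == "intron") res <- rbind(res, c(pos, pos + len))
    if (.OP_REF[op]) pos <- pos + len
  }
  if (is.null(res)) res <- matrix(integer(0), ncol = 2)
  dimnames(res) <- list(NULL, c("donor_end", "acceptor_start"))
  res
}

#' Read base observed at a target position
#'
#' Walks the operation list to report what the read shows at a single target
#' (genomic or transcript) position.
#'
#' @param aln A [read_alignment()] carrying `seq`.
#' @param pos 0-based target position.
#' @return A list with `status` (`"base"`, `"deleted"`, `"spliced"` or
#'   `"outside"`) and `base` (the read base, or `NA`).
#' @export
read_base_at <- function(aln, pos) {
  r <- aln$target_start
  q <- 0L
  if (pos < r) return(list(status = "outside", base = NA_character_))
  for (i in seq_len(nrow(aln$ops))) {
    op <- aln$ops$op[i]; len <- aln$ops$len[i]
    ref_c <- .OP_REF[[op]]; read_c <- .OP_READ[[op]]
    if (ref_c && pos < r + len) {
      if (op == "intron")
        return(list(status = "spliced", base = NA_character_))
      if (op == "deletion")
        return(list(status = "deleted", base = NA_character_))
      b <- if (is.null(aln$seq)) NA_character_ else
        substr(aln$seq, q + (pos - r) + 1L, q + (pos - r) + 1L)
      return(list(status = "base", base = b))
    }
    if (ref_c) r <- r + len
    if (read_c) q <- q + len
  }
  list(status = "outside", base = NA_character_)
}

#' @noRd
.ops_to_cigar <- function(ops) {
  paste0(paste0(ops$len, .OP_CIG[ops$op]), collapse = "")
}

#' @noRd
.cigar_to_ops <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  keep <- !ops %in% c("S", "H", "P")
  nclip_lead <- if (length(ops) && ops[1] == "S") lens[1] else 0L
  nclip_tail <- if (length(ops) > 1 && ops[length(ops)] == "S")
    lens[length(ops)] else 0L
  list(ops = data.frame(op = unname(.CIG_OP[ops[keep]]), len = lens[keep],
                        stringsAsFactors = FALSE),
       clip = c(nclip_lead, nclip_tail))
}

#' Read alignments from SAM/BAM
#'
#' Loads mapped records into [read_alignment()] objects. SAM files are
#' converted to BAM on the fly. CIGARs using `=`/`X` retain match/mismatch
#' distinction; plain `M` runs are treated as matches (align with `--eqx`
#' or regenerate mismatch information upstream when fidelity scoring is
#' required). Soft-clipped bases are removed from the stored sequence,
#' hard clips ignored. `HP`/`PS` tags are carried into `tags`.
#'
#' @param path SAM or BAM file.
#' @param target_kind `"transcript"` or `"genome"` (what the reads were
#'   aligned to).
#' @return List of [read_alignment()] objects.
#' @export
read_sam_alignments <- function(path, target_kind = c("genome", "transcript")) {
  target_kind <- match.arg(target_kind)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "strand", "pos", "mapq", "cigar", "seq"),
    tag = c("HP", "PS"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(rec$qname)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cg <- .cigar_to_ops(rec$cigar[i])
    s <- as.character(rec$seq[i])
    s <- substr(s, cg$clip[1] + 1L, nchar(s) - cg$clip[2])
    tags <- list()
    if (!is.null(rec$tag$HP) && !is.na(rec$tag$HP[i]))
      tags$HP <- rec$tag$HP[i]
    if (!is.null(rec$tag$PS) && !is.na(rec$tag$PS[i]))
      tags$PS <- as.character(rec$tag$PS[i])
    out[[i]] <- read_alignment(
      read_id = rec$qname[i], target_id = as.character(rec$rname[i]),
      target_kind = target_kind, target_start = rec$pos[i] - 1L,
      ops = cg$ops, mapq = rec$mapq[i], seq = s,
      strand = as.character(rec$strand[i]), tags = tags)
  }
  out
}

#' Write read alignments as SAM
#'
#' Minimal SAM 1.6 writer used to export simulated alignments; output is
#' accepted by samtools and [read_sam_alignments()]. CIGARs use `=`/`X`.
#'
#' @param alns List of [read_alignment()].
#' @param path Output path.
#' @param target_lengths Named integer vector of target sequence lengths
#'   (for the `@SQ` header lines).
#' @export
write_sam <- function(alns, path, target_lengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(target_lengths),
                     as.integer(target_lengths)), con)
  for (a in alns) {
    flag <- if (a$strand == "-") 16L else 0L
    extra <- character(0)
    if (!is.null(a$tags$HP)) extra <- c(extra, sprintf("HP:i:%d", a$tags$HP))
    if (!is.null(a$tags$PS)) extra <- c(extra, sprintf("PS:Z:%s", a$tags$PS))
    line <- paste(c(a$read_id, flag, a$target_id, a$target_start + 1L,
                    a$mapq, .ops_to_cigar(a$ops), "*", 0L, 0L,
                    if (is.null(a$seq)) "*" else a$seq, "*", extra),
                  collapse = "\t")
    writeLines(line, con)
  }
  invisible(path)
}

#' Project a genomic read alignment onto a transcript model
#'
#' Exact realignment-by-projection: the read's genomic alignment is mapped
#' through the model's exon structure into transcript coordinates. The read
#' is a valid candidate for the model only if every read splice junction
#' exactly matches a model junction and no aligned read base falls inside a
#' model intron; bases beyond the model span are clipped (excluded from the
#' aligned-base accounting, like soft clips). Used for annotation-reliant
#' assignment and for realignment to first-pass isoforms.
#'
#' @param aln A genome-target [read_alignment()].
#' @param model A [transcript_model()] on the same chromosome.
#' @return A transcript-target [read_alignment()] (in transcript
#'   orientation), or `NULL` when the read is incompatible with the model.
#' @export
project_to_transcript <- function(aln, model) {
  stopifnot(aln$target_kind == "genome")
  if (!identical(aln$target_id, model$chrom)) return(NULL)
  ex <- model$exons
  span <- c(ex[1, 1], ex[nrow(ex), 2])
  modj <- tx_junctions(model)
  modj_key <- paste(modj[, 1], modj[, 2])
  rj <- read_junctions(aln)
  if (nrow(rj) > 0 && !all(paste(rj[, 1], rj[, 2]) %in% modj_key))
    return(NULL)

  lens <- ex[, 2] - ex[, 1]
  before <- c(0L, cumsum(lens))[seq_len(nrow(ex))]
  L <- sum(lens)
  # plus-layout transcript offset of genomic position g (g must be exonic)
  pt_of <- function(g) {
    i <- which(g >= ex[, 1] & g < ex[, 2])
    before[i] + (g - ex[i, 1])
  }
  in_intron <- function(g1, g2) {
    # does [g1,g2) overlap the model span but escape the exons?
    g1c <- max(g1, span[1]); g2c <- min(g2, span[2])
    if (g1c >= g2c) return(FALSE)
    cov <- 0L
    for (i in seq_len(nrow(ex))) {
      o <- min(g2c, ex[i, 2]) - max(g1c, ex[i, 1])
      if (o > 0) cov <- cov + o
    }
    cov < (g2c - g1c)
  }

  r <- aln$target_start
  segs <- NULL   # rows: op_index_type, pt_start, len (plus layout)
  for (i in seq_len(nrow(aln$ops))) {
    op <- aln$ops$op[i]; len <- aln$ops$len[i]
    if (op == "intron") { r <- r + len; next }
    if (op == "insertion") {
      if (r > span[1] && r < span[2] && !in_intron(r - 1L, r)) {
        pt <- pt_of(r - 1L) + 1L
        segs <- rbind(segs, c(2L, pt, len))
      }
      next
    }
    # ref-consuming block [r, r+len)
    if (in_intron(r, r + len)) return(NULL)
    g1 <- max(r, span[1]); g2 <- min(r + len, span[2])
    if (g1 < g2) {
      code <- switch(op, match = 0L, mismatch = 1L, deletion = 3L)
      segs <- rbind(segs, c(code, pt_of(g1), g2 - g1))
    }
    r <- r + len
  }
  if (is.null(segs) || !any(segs[, 1] %in% c(0L, 1L))) return(NULL)

  ops_chr <- c("match", "mismatch", "insertion", "deletion")
  if (model$strand == "-") {
    # flip to transcript orientation: interval [pt, pt+len) -> [L-pt-len, L-pt)
    ref_len <- ifelse(segs[, 1] == 2L, 0L, segs[, 3])
    segs[, 2] <- L - segs[, 2] - ref_len
    segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  }
  segs <- segs[order(segs[, 2]), , drop = FALSE]
  t_start <- segs[which(segs[, 1] != 2L)[1], 2]
  ops <- data.frame(op = ops_chr[segs[, 1] + 1L], len = segs[, 3],
                    stringsAsFactors = FALSE)
  # merge adjacent identical ops
  if (nrow(ops) > 1) {
    keep <- c(TRUE, ops$op[-1] != ops$op[-nrow(ops)])
    grp <- cumsum(keep)
    ops <- data.frame(op = ops$op[keep],
                      len = as.integer(tapply(ops$len, grp, sum)),
                      stringsAsFactors = FALSE)
  }
  read_alignment(aln$read_id, model$transcript_id, "transcript",
                 target_start = t_start, ops = ops, mapq = aln$mapq,
                 strand = "+", tags = aln$tags)
}
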