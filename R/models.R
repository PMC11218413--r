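#' Transcript model
#'
#' A transcript model is a gene id, a strand and an ordered set of exons on
#' one chromosome. All coordinates in the package are 0-based half-open;
#' conversion to/from 1-based closed conventions happens only at the GTF/VCF
#' format boundary. Exons are stored in ascending genomic order regardless of
#' strand; transcript-orientation quantities (5' end, junction offsets) are
#' derived on demand.
#'
#' @param transcript_id,gene_id Character scalars.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end), 0-based half-open, ascending
#'   and non-overlapping.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  stopifnot(nzchar(chrom), strand %in% c("+", "-"),
            all(exons[, 1] < exons[, 2]))
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons in transcript ", transcript_id)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons),
            class = "transcript_model")
}

#' @exportS3Method base::print
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s%s  %d exon(s), %d bp\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), tx_length(x)))
  invisible(x)
}

#' Spliced length of a transcript model
#' @param model A [transcript_model()].
#' @return Integer, the sum of exon widths.
#' @export
tx_length <- function(model) sum(model$exons[, 2] - model$exons[, 1])

#' Splice junctions of a transcript model
#'
#' @param model A [transcript_model()].
#' @return Integer matrix with columns `donor_end`, `acceptor_start` (genomic
#'   coordinates of the gaps between consecutive exons, ascending); zero rows
#'   for single-exon models.
#' @export
tx_junctions <- function(model) {
  m <- nrow(model$exons)
  if (m < 2)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("donor_end", "acceptor_start"))))
  cbind(donor_end = model$exons[-m, 2], acceptor_start = model$exons[-1, 1])
}

#' Junction offsets in transcript coordinates
#'
#' Positions (0-based) in transcript orientation at which an exon/exon
#' boundary falls: base `c-1` is the last base of one exon, base `c` the
#' first of the next.
#' @noRd
.tx_junction_offsets <- function(model) {
  lens <- model$exons[, 2] - model$exons[, 1]
  m <- length(lens)
  if (m < 2) return(integer(0))
  cs <- cumsum(lens)[-m]              # plus-layout offsets
  if (model$strand == "+") cs else sort(sum(lens) - cs)
}

#' Map genomic positions to transcript coordinates
#'
#' @param model A [transcript_model()].
#' @param gpos Integer vector of genomic positions (0-based).
#' @return Integer vector of transcript-orientation offsets (0-based, 0 = 5'
#'   end of the transcript); `NA` for positions outside the exons.
#' @export
genome_to_tx <- function(model, gpos) {
  ex <- model$exons
  lens <- ex[, 2] - ex[, 1]
  before <- c(0L, cumsum(lens))[seq_len(nrow(ex))]
  pt <- rep(NA_integer_, length(gpos))
  for (i in seq_len(nrow(ex))) {
    hit <- !is.na(gpos) & gpos >= ex[i, 1] & gpos < ex[i, 2]
    pt[hit] <- before[i] + (gpos[hit] - ex[i, 1])
  }
  if (model$strand == "-") ifelse(is.na(pt), NA_integer_,
                                  sum(lens) - 1L - pt) else pt
}

#' Junction-chain key of a transcript model
#'
#' Canonical string identifying the ordered splice junctions of a model;
#' the grouping key used throughout collapse.
#' @param model A [transcript_model()].
#' @return Character scalar, e.g. `"chr1:200-300,450-700"`; single-exon models
#'   yield `"chr1:."`.
#' @export
junction_chain <- function(model) {
  j <- tx_junctions(model)
  if (nrow(j) == 0) return(paste0(model$chrom, ":."))
  paste0(model$chrom, ":",
         paste(paste0(j[, 1], "-", j[, 2]), collapse = ","))
}
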