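#' Splice-fidelity metrics of a read-to-transcript alignment
#'
#' Quantifies how faithfully a read supports a transcript model: the global
#' match fraction, whether the alignment reaches both transcript ends, and
#' per-junction quality. For every splice junction (at transcript offset
#' `c`), the six flanking bases are positions `c-3 .. c+2`; the metric counts
#' how many of them are matched, and the size of the largest indel whose
#' footprint touches that window. A junction whose window is not fully inside
#' the aligned span is recorded as uncovered (`NA`), which is distinct from a
#' covered-but-mismatched window.
#'
#' @param aln A transcript-target [read_alignment()].
#' @param model The corresponding [transcript_model()].
#' @param end_window Maximum distance (bp) from the transcript 5'/3' end at
#'   which the alignment may start/end and still count as covering the
#'   first/last exon (default 25).
#' @return An object of class `fidelity_metrics`: a list with
#'   `match_fraction`, `covers_first_exon`, `covers_last_exon`,
#'   `junction_flank_matches` (integer, `NA` = uncovered),
#'   `junction_max_indel`, `matched_bases`, `aligned_bases`.
#' @export
compute_fidelity <- function(aln, model, end_window = 25L) {
  stopifnot(aln$target_kind == "transcript")
  L <- tx_length(model)
  joff <- .tx_junction_offsets(model)

  t <- aln$target_start
  matched <- 0L; mismatched <- 0L; inserted <- 0L
  match_iv <- NULL                       # rows: start, end (target coords)
  indels <- NULL                         # rows: start, end, len (footprint)
  for (i in seq_len(nrow(aln$ops))) {
    op <- aln$ops$op[i]; len <- aln$ops$len[i]
    switch(op,
      match = {
        matched <- matched + len
        match_iv <- rbind(match_iv, c(t, t + len))
        t <- t + len
      },
      mismatch = { mismatched <- mismatched + len; t <- t + len },
      insertion = {
        inserted <- inserted + len
        indels <- rbind(indels, c(t, t, len))
      },
      deletion = {
        indels <- rbind(indels, c(t, t + len, len))
        t <- t + len
      },
      stop("unexpected op in transcript alignment: ", op))
  }
  t_end <- t
  aligned <- matched + mismatched + inserted
  mf <- if (aligned > 0) matched / aligned else 0

  flank <- rep(NA_integer_, length(joff))
  maxind <- rep(0L, length(joff))
  for (k in seq_along(joff)) {
    w1 <- joff[k] - 3L; w2 <- joff[k] + 3L       # window [w1, w2)
    if (w1 < aln$target_start || w2 > t_end) next # uncovered
    hit <- 0L
    for (r in seq_len(NROW(match_iv))) {
      o <- min(w2, match_iv[r, 2]) - max(w1, match_iv[r, 1])
      if (o > 0) hit <- hit + o
    }
    flank[k] <- hit
    for (r in seq_len(NROW(indels))) {
      touches <- if (indels[r, 1] == indels[r, 2])  # insertion point
        indels[r, 1] >= w1 && indels[r, 1] <= w2
      else
        indels[r, 1] < w2 && indels[r, 2] > w1
      if (touches) maxind[k] <- max(maxind[k], indels[r, 3])
    }
  }

  first_ok <- aln$target_start <= end_window
  last_ok <- (L - t_end) <= end_window
  structure(list(match_fraction = mf,
                 covers_first_exon = first_ok,
                 covers_last_exon = last_ok,
                 junction_flank_matches = flank,
                 junction_max_indel = maxind,
                 matched_bases = matched,
                 aligned_bases = aligned),
            class = "fidelity_metrics")
}

#' Stringent read-support rule
#'
#' A read supports a transcript under the stringent rule when at least
#' `min_match` of its aligned bases match the transcript and the alignment
#' reaches within the end window of both the first and the last exon.
#' Boundaries are inclusive: a match fraction of exactly 0.80 passes.
#'
#' @param m A `fidelity_metrics` object from [compute_fidelity()].
#' @param min_match Minimum matched fraction of aligned read bases
#'   (default 0.8).
#' @return Logical scalar.
#' @export
passes_stringent <- function(m, min_match = 0.8) {
  m$match_fraction >= min_match && m$covers_first_exon && m$covers_last_exon
}

#' Splice-site check rule
#'
#' A read passes when *every* junction of the transcript has at least
#' `min_flank` of its six flanking bases matched and no indel larger than
#' `max_indel` bp touching the splice-site window. A junction not covered by
#' the alignment fails the read for this transcript: a supporting read must
#' provide evidence across the entire isoform.
#'
#' @param m A `fidelity_metrics` object.
#' @param min_flank Minimum matched flanking bases out of 6 (default 4).
#' @param max_indel Largest tolerated indel at a splice site (default 3 bp).
#' @return Logical scalar.
#' @export
passes_check_splice <- function(m, min_flank = 4L, max_indel = 3L) {
  f <- m$junction_flank_matches
  if (length(f) == 0) return(TRUE)
  if (anyNA(f)) return(FALSE)
  all(f >= min_flank) && all(m$junction_max_indel <= max_indel)
}

#' Assign a read to its best transcript
#'
#' Among the candidate alignments tied at the maximum mapping quality, keeps
#' those passing both the stringent and splice-check rules and returns the
#' transcript with the highest match fraction. Ties break deterministically:
#' larger matched-base count, then lexicographically smallest transcript id.
#'
#' @param read_id Read identifier (candidates must all belong to it).
#' @param candidates List of transcript-target [read_alignment()].
#' @param models Named list of [transcript_model()] (by transcript id).
#' @param min_match,end_window Stringent-rule parameters.
#' @param min_flank,max_indel Splice-check parameters.
#' @return The winning transcript id, or `NA_character_` when no candidate
#'   passes (the read is forwarded to novel isoform detection).
#' @export
assign_read <- function(read_id, candidates, models, min_match = 0.8,
                        end_window = 25L, min_flank = 4L, max_indel = 3L) {
  if (length(candidates) == 0) return(NA_character_)
  stopifnot(all(vapply(candidates, `[[`, "", "read_id") == read_id))
  mapqs <- vapply(candidates, `[[`, 0L, "mapq")
  top <- candidates[mapqs == max(mapqs)]
  best <- NULL
  for (cand in top) {
    mod <- models[[cand$target_id]]
    if (is.null(mod)) stop("no model for target ", cand$target_id)
    m <- compute_fidelity(cand, mod, end_window = end_window)
    if (!passes_stringent(m, min_match = min_match)) next
    if (!passes_check_splice(m, min_flank = min_flank,
                             max_indel = max_indel)) next
    rec <- list(id = cand$target_id, mf = m$match_fraction,
                mb = m$matched_bases)
    if (is.null(best) ||
        rec$mf > best$mf ||
        (rec$mf == best$mf && rec$mb > best$mb) ||
        (rec$mf == best$mf && rec$mb == best$mb && rec$id < best$id))
      best <- rec
  }
  if (is.null(best)) NA_character_ else best$id
}

#' Annotation-reliant assignment of genomic read alignments
#'
#' Projects each read's genomic alignment onto every compatible annotated
#' transcript (exact junction agreement; see [project_to_transcript()]) and
#' assigns it with [assign_read()]. This is the annotation branch of isoform
#' detection; reads aligned to transcript sequences by an external aligner
#' can be fed to [assign_read()] directly via [read_sam_alignments()].
#'
#' @param alns List of genome-target [read_alignment()].
#' @param models Named list of [transcript_model()].
#' @param ... Passed to [assign_read()].
#' @return Named character vector read id -> transcript id (`NA` for
#'   unassigned reads).
#' @export
assign_to_annotation <- function(alns, models, ...) {
  # index models by chromosome, with spans for a cheap overlap pre-filter
  chroms <- vapply(models, `[[`, "", "chrom")
  spans <- t(vapply(models, function(m)
    c(m$exons[1, 1], m$exons[nrow(m$exons), 2]), c(0, 0)))
  out <- setNames(rep(NA_character_, length(alns)),
                  vapply(alns, `[[`, "", "read_id"))
  for (i in seq_along(alns)) {
    a <- alns[[i]]
    sel <- which(chroms == a$target_id &
                   spans[, 1] < aln_target_end(a) &
                   spans[, 2] > a$target_start)
    cands <- list()
    for (j in sel) {
      pr <- project_to_transcript(a, models[[j]])
      if (!is.null(pr)) cands[[length(cands) + 1L]] <- pr
    }
    out[i] <- assign_read(a$read_id, cands, models, ...)
  }
  out
}

#' Filter annotated isoforms by read support
#'
#' Keeps transcripts with at least `min_support` assigned reads; reads of
#' dropped transcripts are returned to the unassigned pool. Every input read
#' ends up in exactly one of the two outputs.
#'
#' @param assignments Named character vector read -> transcript
#'   (`NA` = unassigned), as from [assign_to_annotation()].
#' @param min_support Minimum supporting read count (default 3).
#' @return List with `supported` (named list transcript id -> character
#'   vector of read ids) and `unassigned` (character vector of read ids).
#' @export
supported_annotated_isoforms <- function(assignments, min_support = 3L) {
  hit <- !is.na(assignments)
  tab <- split(names(assignments)[hit], assignments[hit])
  keep <- vapply(tab, length, 0L) >= min_support
  list(supported = tab[keep],
       unassigned = c(names(assignments)[!hit],
                      unlist(tab[!keep], use.names = FALSE)))
}

#' Write a read-to-isoform map as TSV
#'
#' One line per isoform: `isoform_id<TAB>read1,read2,...`.
#' @param read_map Named list isoform id -> character vector of read ids.
#' @param path Output path.
#' @export
write_read_map <- function(read_map, path) {
  lines <- vapply(seq_along(read_map), function(i)
    paste0(names(read_map)[i], "\t",
           paste(read_map[[i]], collapse = ",")), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a read-to-isoform map TSV written by [write_read_map()]
#' @param path Input path.
#' @return Named list isoform id -> character vector of read ids.
#' @export
parse_read_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) strsplit(p[2], ",", fixed = TRUE)[[1]]),
           vapply(parts, `[[`, "", 1))
}
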