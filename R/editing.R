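#' Candidate inosine sites from variant calls
#'
#' A-to-I editing appears as A>G mismatches on the transcribed strand, so a
#' genomic variant is a candidate inosine when it is A>G inside a
#' forward-strand gene or T>C inside a reverse-strand gene. Strand is
#' resolved against gene annotation: variants in unannotated or
#' ambiguous-strand regions are dropped (counted). An optional known-sites
#' BED (e.g. an editing database export) sets the `in_known` flag.
#'
#' @param variants `data.frame` from [parse_vcf()] (union over callers).
#' @param models Named list of [transcript_model()] (gene strand source).
#' @param known_sites Optional `data.frame` with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return `data.frame` of sites: `chrom`, `pos`, `ref`, `alt`,
#'   `gene_strand`, `edited_base` (the base an edited read shows on the
#'   genome forward strand), `in_known`; with attribute `n_dropped`.
#' @export
candidate_inosines <- function(variants, models, known_sites = NULL) {
  genes <- list()
  for (m in models) {
    g <- genes[[m$gene_id]]
    span <- c(m$exons[1, 1], m$exons[nrow(m$exons), 2])
    if (is.null(g))
      genes[[m$gene_id]] <- list(chrom = m$chrom, strand = m$strand,
                                 start = span[1], end = span[2])
    else
      genes[[m$gene_id]] <- list(chrom = g$chrom, strand = g$strand,
                                 start = min(g$start, span[1]),
                                 end = max(g$end, span[2]))
  }
  gdf <- data.frame(chrom = vapply(genes, `[[`, "", "chrom"),
                    strand = vapply(genes, `[[`, "", "strand"),
                    start = vapply(genes, function(g) g$start, 0),
                    end = vapply(genes, function(g) g$end, 0))
  keep <- logical(nrow(variants))
  strand <- character(nrow(variants))
  dropped <- 0L
  for (i in seq_len(nrow(variants))) {
    hit <- gdf$chrom == variants$chrom[i] & gdf$start <= variants$pos[i] &
      gdf$end > variants$pos[i]
    st <- unique(gdf$strand[hit])
    if (length(st) != 1) { dropped <- dropped + 1L; next }
    ok <- (st == "+" && variants$ref[i] == "A" && variants$alt[i] == "G") ||
      (st == "-" && variants$ref[i] == "T" && variants$alt[i] == "C")
    if (ok) { keep[i] <- TRUE; strand[i] <- st }
  }
  out <- variants[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  out$gene_strand <- strand[keep]
  out$edited_base <- out$alt
  out$in_known <- FALSE
  if (!is.null(known_sites) && nrow(out) > 0) {
    for (i in seq_len(nrow(out)))
      out$in_known[i] <- any(known_sites$chrom == out$chrom[i] &
                               known_sites$start <= out$pos[i] &
                               known_sites$end > out$pos[i])
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Pileup edited/unedited read counts at candidate sites
#'
#' For each site, counts reads showing the edited base and reads showing the
#' reference base, per condition (replicates of a condition are supplied
#' together and summed). Reads showing any other base, or a deletion, are
#' excluded from both counts; reads whose alignment splices across the
#' position (the site strictly inside an intron operation) are tallied in
#' `spliced_out` (pooled over conditions). Sites with no overlapping reads
#' are retained with zero counts.
#'
#' @param aln_sets Named list with elements `ctrl` and `kd`, each a list of
#'   genome-target [read_alignment()] with sequences.
#' @param sites `data.frame` from [candidate_inosines()].
#' @return `data.frame` of per-site counts: `chrom`, `pos`, `gene_strand`,
#'   `edited_ctrl`, `unedited_ctrl`, `edited_kd`, `unedited_kd`,
#'   `spliced_out`.
#' @export
pileup_counts <- function(aln_sets, sites) {
  stopifnot(all(c("ctrl", "kd") %in% names(aln_sets)))
  n <- nrow(sites)
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    gene_strand = sites$gene_strand,
                    edited_ctrl = integer(n), unedited_ctrl = integer(n),
                    edited_kd = integer(n), unedited_kd = integer(n),
                    spliced_out = integer(n), stringsAsFactors = FALSE)
  for (cond in c("ctrl", "kd")) {
    ecol <- paste0("edited_", cond)
    ucol <- paste0("unedited_", cond)
    for (a in aln_sets[[cond]]) {
      lo <- a$target_start; hi <- aln_target_end(a)
      for (i in seq_len(n)) {
        if (sites$chrom[i] != a$target_id ||
            sites$pos[i] < lo || sites$pos[i] >= hi) next
        b <- read_base_at(a, sites$pos[i])
        if (b$status == "spliced") {
          out$spliced_out[i] <- out$spliced_out[i] + 1L
        } else if (b$status == "base" && !is.na(b$base)) {
          if (b$base == sites$edited_base[i])
            out[[ecol]][i] <- out[[ecol]][i] + 1L
          else if (b$base == sites$ref[i])
            out[[ucol]][i] <- out[[ucol]][i] + 1L
        }
      }
    }
  }
  out
}

#' Differential editing between knockdown and control
#'
#' Two-sided Fisher exact test on `[[edited_kd, unedited_kd],
#' [edited_ctrl, unedited_ctrl]]` per site. A site is called significantly
#' changed when coverage is at least `min_cov` in either condition
#' (disjunction), the edited-fraction change is at least `min_delta` in
#' magnitude, and the raw p-value is below `alpha` (no multiple-testing
#' correction, matching the long-read discovery design). Zero-coverage
#' fractions are defined as 0 and flagged.
#'
#' @param counts `data.frame` from [pileup_counts()].
#' @param min_cov Minimum coverage in either condition (default 10).
#' @param min_delta Minimum |edited-fraction difference| (default 0.10).
#' @param alpha Raw p-value threshold (default 0.05).
#' @return Input with added columns `cov_ctrl`, `cov_kd`, `frac_ctrl`,
#'   `frac_kd`, `zero_cov_flag`, `delta`, `p_value`, `direction`
#'   (`"down"`/`"up"` after knockdown) and `significant`.
#' @export
differential_editing <- function(counts, min_cov = 10L, min_delta = 0.10,
                                 alpha = 0.05) {
  n <- nrow(counts)
  counts$cov_ctrl <- counts$edited_ctrl + counts$unedited_ctrl
  counts$cov_kd <- counts$edited_kd + counts$unedited_kd
  counts$zero_cov_flag <- counts$cov_ctrl == 0 | counts$cov_kd == 0
  counts$frac_ctrl <- ifelse(counts$cov_ctrl > 0,
                             counts$edited_ctrl / counts$cov_ctrl, 0)
  counts$frac_kd <- ifelse(counts$cov_kd > 0,
                           counts$edited_kd / counts$cov_kd, 0)
  counts$delta <- counts$frac_kd - counts$frac_ctrl
  counts$p_value <- vapply(seq_len(n), function(i)
    fisher2x2(counts$edited_kd[i], counts$unedited_kd[i],
              counts$edited_ctrl[i], counts$unedited_ctrl[i])$p, 0)
  counts$direction <- ifelse(counts$delta < 0, "down", "up")
  counts$significant <- (counts$cov_ctrl >= min_cov |
                           counts$cov_kd >= min_cov) &
    abs(counts$delta) >= min_delta & counts$p_value < alpha
  counts
}

#' Type I hyperediting classification
#'
#' A site is type I hyperedited in a condition when strictly more than
#' `threshold` of its covering (edited + unedited) reads are edited.
#' Zero-coverage sites are not type I (flagged).
#'
#' @param counts `data.frame` from [pileup_counts()].
#' @param threshold Edited fraction that must be exceeded (default 0.40).
#' @return Input with logical columns `type1_ctrl`, `type1_kd` and
#'   `type1_zero_cov`.
#' @export
classify_type1 <- function(counts, threshold = 0.40) {
  cc <- counts$edited_ctrl + counts$unedited_ctrl
  ck <- counts$edited_kd + counts$unedited_kd
  counts$type1_ctrl <- cc > 0 & counts$edited_ctrl > threshold * cc
  counts$type1_kd <- ck > 0 & counts$edited_kd > threshold * ck
  counts$type1_zero_cov <- cc == 0 | ck == 0
  counts
}

#' Type II hyperediting regions
#'
#' Finds regions with at least `min_sites` edit sites within every
#' `window` bp: candidate windows are anchored at each site (any qualifying
#' window can be slid right to start at a site without losing sites);
#' windows containing >= `min_sites` sites qualify, overlapping qualifying
#' windows merge into maximal regions, and each region's bounds are the
#' min/max site positions it contains.
#'
#' @param sites `data.frame` with `chrom` and `pos` (one row per edit site).
#' @param window Window width in bp (default 150).
#' @param min_sites Minimum edits per window (default 3).
#' @return `data.frame` of regions: `chrom`, `start`, `end` (positions of the
#'   outermost sites, inclusive), `n_edits`, and a `site_pos` list-column.
#' @export
type2_regions <- function(sites, window = 150L, min_sites = 3L) {
  rows <- list()
  for (chrom in unique(sites$chrom)) {
    p <- sort(unique(sites$pos[sites$chrom == chrom]))
    n <- length(p)
    spans <- NULL
    j <- 1L
    for (i in seq_len(n)) {
      if (j < i) j <- i
      while (j < n && p[j + 1L] <= p[i] + window - 1L) j <- j + 1L
      if (j - i + 1L >= min_sites)
        spans <- rbind(spans, c(p[i], p[i] + window))  # half-open span
    }
    if (is.null(spans)) next
    # merge overlapping/adjacent window spans
    ord <- order(spans[, 1])
    spans <- spans[ord, , drop = FALSE]
    cur <- spans[1, ]
    flush <- function(cur) {
      inside <- p[p >= cur[1] & p < cur[2]]
      data.frame(chrom = chrom, start = min(inside), end = max(inside),
                 n_edits = length(inside), stringsAsFactors = FALSE)
    }
    merged <- list()
    for (r in seq_len(nrow(spans))[-1]) {
      if (spans[r, 1] <= cur[2]) cur[2] <- max(cur[2], spans[r, 2])
      else { merged[[length(merged) + 1L]] <- flush(cur); cur <- spans[r, ] }
    }
    merged[[length(merged) + 1L]] <- flush(cur)
    for (mr in merged) {
      mr$site_pos <- list(p[p >= mr$start & p <= mr$end])
      rows[[length(rows) + 1L]] <- mr
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_edits = integer())
    out$site_pos <- list()
  }
  rownames(out) <- NULL
  out
}

#' Per-read edit profiles at candidate sites
#'
#' @param alns List of genome-target [read_alignment()] with sequences.
#' @param sites `data.frame` from [candidate_inosines()].
#' @return Character matrix reads x sites with values `"edited"`,
#'   `"unedited"` or `NA` (site not assessable on that read); columns named
#'   `chrom:pos`.
#' @export
edit_profiles <- function(alns, sites) {
  n <- nrow(sites)
  prof <- matrix(NA_character_, nrow = length(alns), ncol = n,
                 dimnames = list(vapply(alns, `[[`, "", "read_id"),
                                 paste0(sites$chrom, ":", sites$pos)))
  for (ri in seq_along(alns)) {
    a <- alns[[ri]]
    lo <- a$target_start; hi <- aln_target_end(a)
    for (i in seq_len(n)) {
      if (sites$chrom[i] != a$target_id ||
          sites$pos[i] < lo || sites$pos[i] >= hi) next
      b <- read_base_at(a, sites$pos[i])
      if (b$status == "base" && !is.na(b$base)) {
        if (b$base == sites$edited_base[i]) prof[ri, i] <- "edited"
        else if (b$base == sites$ref[i]) prof[ri, i] <- "unedited"
      }
    }
  }
  prof
}

#' Single-molecule co-editing (coordination) test
#'
#' For each site, its up-to-`k_nearest` nearest candidate sites at least
#' `min_dist` bp away (same chromosome) define candidate pairs; the union of
#' the directed neighbourhoods is tested, each unordered pair once. Over the
#' reads assessable at both positions, a 2x2 table of (edited/unedited at
#' site 1) x (edited/unedited at site 2) is tested with a two-sided Fisher
#' exact test; pairs with p < `alpha` are reported as coordinated. No
#' multiple-testing correction is applied.
#'
#' @param profiles Matrix from [edit_profiles()].
#' @param sites The matching `data.frame` of sites.
#' @param min_dist Minimum pair distance in bp (default 50).
#' @param k_nearest Neighbourhood size per site (default 20).
#' @param alpha Significance threshold (default 0.05).
#' @return `data.frame` of tested pairs: positions, the four table cells
#'   (`both`, `only1`, `only2`, `neither`), `n_reads`, `p_value`,
#'   `coordinated`; attribute `n_skipped` counts pairs with no doubly
#'   covered read.
#' @export
coordination_test <- function(profiles, sites, min_dist = 50L,
                              k_nearest = 20L, alpha = 0.05) {
  n <- nrow(sites)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_len(n)) {
    same <- which(sites$chrom == sites$chrom[i])
    d <- abs(sites$pos[same] - sites$pos[i])
    elig <- same[d >= min_dist]
    if (length(elig) == 0) next
    dd <- abs(sites$pos[elig] - sites$pos[i])
    ord <- order(dd, sites$pos[elig])
    nb <- elig[ord][seq_len(min(k_nearest, length(elig)))]
    pairs <- rbind(pairs, cbind(pmin(i, nb), pmax(i, nb)))
  }
  pairs <- unique(pairs)
  rows <- list()
  skipped <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    pi <- profiles[, i]; pj <- profiles[, j]
    ok <- !is.na(pi) & !is.na(pj)
    if (sum(ok) < 1) { skipped <- skipped + 1L; next }
    both <- sum(pi[ok] == "edited" & pj[ok] == "edited")
    only1 <- sum(pi[ok] == "edited" & pj[ok] == "unedited")
    only2 <- sum(pi[ok] == "unedited" & pj[ok] == "edited")
    neither <- sum(pi[ok] == "unedited" & pj[ok] == "unedited")
    ft <- fisher2x2(both, only1, only2, neither)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = sites$chrom[i], pos1 = sites$pos[i], pos2 = sites$pos[j],
      both = both, only1 = only1, only2 = only2, neither = neither,
      n_reads = sum(ok), p_value = ft$p, coordinated = ft$p < alpha,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos1 = integer(),
                      pos2 = integer(), both = integer(), only1 = integer(),
                      only2 = integer(), neither = integer(),
                      n_reads = integer(), p_value = numeric(),
                      coordinated = logical())
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

#' Edit/splice mutual-exclusivity table
#'
#' Sites where editing and splicing compete: type I hyperedited in the
#' control condition, with at least `min_edited` edited reads (control) and
#' at least `min_spliced` reads whose alignment splices the position out.
#'
#' @param counts `data.frame` from [pileup_counts()] (after
#'   [classify_type1()]; the classification is recomputed if absent).
#' @param min_edited Minimum edited reads (default 10).
#' @param min_spliced Minimum spliced-out reads (default 10).
#' @param threshold Type I threshold when recomputing (default 0.40).
#' @return Filtered `data.frame` with columns `chrom`, `pos`, `unedited`,
#'   `edited`, `spliced_out` (intronic-editing table layout).
#' @export
intron_editing <- function(counts, min_edited = 10L, min_spliced = 10L,
                           threshold = 0.40) {
  if (is.null(counts$type1_ctrl))
    counts <- classify_type1(counts, threshold = threshold)
  keep <- counts$type1_ctrl & counts$edited_ctrl >= min_edited &
    counts$spliced_out >= min_spliced
  out <- data.frame(chrom = counts$chrom[keep], pos = counts$pos[keep],
                    unedited = counts$unedited_ctrl[keep],
                    edited = counts$edited_ctrl[keep],
                    spliced_out = counts$spliced_out[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write the differential-editing site table (edit-counts layout)
#'
#' Columns: chromosome, position, control unedited, control edited,
#' knockdown unedited, knockdown edited, Fisher p.
#' @param de `data.frame` from [differential_editing()] (typically the
#'   significant subset).
#' @param path Output TSV path.
#' @export
write_editing_table <- function(de, path) {
  df <- de[, c("chrom", "pos", "unedited_ctrl", "edited_ctrl",
               "unedited_kd", "edited_kd", "p_value")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the intronic-editing table
#' @param tab `data.frame` from [intron_editing()].
#' @param path Output TSV path.
#' @export
write_intron_editing_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
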