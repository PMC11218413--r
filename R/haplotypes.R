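#' Per-read variant profiles for each isoform
#'
#' For every isoform and each supplied SNV falling inside its exons, records
#' what each supporting read shows at the variant's genomic position:
#' `"ref"`, `"alt"`, or `"uncovered"` (a third base, a deletion, a spliced-out
#' position, or a position outside the alignment). Variants outside all exons
#' of an isoform are excluded from that isoform's variant set (logged).
#'
#' @param read_map Named list isoform id -> read ids (from isoform
#'   detection).
#' @param variants `data.frame` with `chrom`, `pos`, `ref`, `alt`
#'   (see [parse_vcf()]).
#' @param alns Named list of genome-target [read_alignment()] carrying
#'   sequences (names = read ids).
#' @param models Named list of [transcript_model()].
#' @return Named list (by isoform) of profile objects: each a list with
#'   `isoform_id`, `variants` (the rows used), and `obs`, a character matrix
#'   reads x variants with values ref/alt/uncovered.
#' @export
profile_reads <- function(read_map, variants, alns, models) {
  out <- list()
  for (iso in names(read_map)) {
    m <- models[[iso]]
    if (is.null(m)) stop("no model for isoform ", iso)
    v <- variants[variants$chrom == m$chrom, , drop = FALSE]
    if (nrow(v) > 0) {
      inside <- !is.na(genome_to_tx(m, v$pos))
      if (any(!inside))
        .msg(sum(!inside), " variant(s) outside exons of ", iso,
             " excluded")
      v <- v[inside, , drop = FALSE]
    }
    reads <- read_map[[iso]]
    obs <- matrix("uncovered", nrow = length(reads), ncol = nrow(v),
                  dimnames = list(reads,
                                  if (nrow(v)) paste0(v$chrom, ":", v$pos)
                                  else NULL))
    for (ri in seq_along(reads)) {
      a <- alns[[reads[ri]]]
      if (is.null(a)) next
      for (vi in seq_len(nrow(v))) {
        b <- read_base_at(a, v$pos[vi])
        if (b$status == "base" && !is.na(b$base)) {
          if (b$base == v$ref[vi]) obs[ri, vi] <- "ref"
          else if (b$base == v$alt[vi]) obs[ri, vi] <- "alt"
        }
      }
    }
    out[[iso]] <- list(isoform_id = iso, variants = v, obs = obs)
  }
  out
}

#' Tabulate haplotypes supported by an isoform's reads
#'
#' Ploidy-agnostic phasing: reads covering every variant site of the isoform
#' are grouped by their exact allele vector; vectors with support of at least
#' `min_support` reads *and* at least `min_fraction` of the isoform's reads
#' are retained (any number of haplotypes may result). A read with uncovered
#' sites is then folded into a retained haplotype only when it is compatible
#' (agrees at all its covered sites) with exactly one of them; otherwise it
#' is discarded. The all-reference vector is a valid haplotype.
#'
#' @param profile One profile from [profile_reads()].
#' @param min_support Minimum reads per haplotype (default 3).
#' @param min_fraction Minimum fraction of the isoform's reads (default
#'   0.10).
#' @return `data.frame` with one row per retained haplotype: `isoform_id`,
#'   `haplotype` (allele vector as a `;`-separated ref/alt string in variant
#'   order), `support`, plus an `alleles` list-column of named character
#'   vectors.
#' @export
tabulate_haplotypes <- function(profile, min_support = 3L,
                                min_fraction = 0.10) {
  obs <- profile$obs
  empty <- data.frame(isoform_id = character(), haplotype = character(),
                      support = integer())
  empty$alleles <- list()
  if (nrow(obs) == 0 || ncol(obs) == 0) return(empty)
  n_reads <- nrow(obs)
  complete <- rowSums(obs == "uncovered") == 0
  if (!any(complete)) return(empty)
  key <- apply(obs[complete, , drop = FALSE], 1, paste, collapse = ";")
  counts <- table(key)
  retained <- names(counts)[counts >= min_support &
                              counts >= min_fraction * n_reads]
  if (length(retained) == 0) return(empty)
  support <- as.integer(counts[retained])
  names(support) <- retained

  # fold partially covered reads into a unique compatible retained haplotype
  ret_mat <- do.call(rbind, strsplit(retained, ";", fixed = TRUE))
  for (ri in which(!complete)) {
    covered <- obs[ri, ] != "uncovered"
    if (!any(covered)) next
    comp <- which(apply(ret_mat, 1, function(h)
      all(h[covered] == obs[ri, covered])))
    if (length(comp) == 1)
      support[comp] <- support[comp] + 1L
  }

  ord <- order(-support, retained)
  out <- data.frame(isoform_id = profile$isoform_id,
                    haplotype = retained[ord],
                    support = unname(support[ord]),
                    stringsAsFactors = FALSE)
  out$alleles <- lapply(strsplit(out$haplotype, ";", fixed = TRUE),
                        function(a) setNames(a, colnames(obs)))
  out
}

#' Tabulate haplotypes across all isoforms
#'
#' @param profiles List of profiles from [profile_reads()].
#' @param ... Passed to [tabulate_haplotypes()].
#' @return Row-bound `data.frame` of haplotype groups.
#' @export
tabulate_all_haplotypes <- function(profiles, ...) {
  res <- lapply(profiles, tabulate_haplotypes, ...)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Phase-set mode: link isoforms to caller-phased haplotypes
#'
#' Uses per-read phase-set (`PS`) and haplotype (`HP`) tags from a diploid
#' phasing variant caller. An isoform is linked to a (phase set, haplotype)
#' when a strict majority (> `majority`) of its tagged reads share it; the
#' phase set's variants falling inside the isoform's exons are attached.
#'
#' @param read_map Named list isoform id -> read ids.
#' @param alns Named list of [read_alignment()] whose `tags` may carry
#'   `HP` (integer) and `PS` (character).
#' @param phase_set_variants `data.frame` of variants with a `phase_set`
#'   column (see [parse_vcf()]).
#' @param models Named list of [transcript_model()].
#' @param majority Fraction that must be exceeded (default 0.5).
#' @return `data.frame` with `isoform_id`, `phase_set`, `haplotype`,
#'   `n_tagged`, `n_linked`, and a `variants` list-column of attached
#'   variant row indices into `phase_set_variants`.
#' @export
phase_set_mode <- function(read_map, alns, phase_set_variants, models,
                           majority = 0.5) {
  rows <- list()
  for (iso in names(read_map)) {
    reads <- read_map[[iso]]
    tags <- lapply(reads, function(r) {
      a <- alns[[r]]
      if (is.null(a) || is.null(a$tags$PS) || is.null(a$tags$HP)) NULL
      else paste0(a$tags$PS, ":", a$tags$HP)
    })
    tags <- unlist(tags)
    if (length(tags) == 0) next   # no tagged reads -> no HST output
    tab <- sort(table(tags), decreasing = TRUE)
    if (tab[1] <= majority * length(tags)) next  # strict majority required
    psh <- strsplit(names(tab)[1], ":", fixed = TRUE)[[1]]
    m <- models[[iso]]
    vsel <- which(phase_set_variants$phase_set == psh[1] &
                    phase_set_variants$chrom == m$chrom &
                    !is.na(genome_to_tx(m, phase_set_variants$pos)))
    if (length(vsel) == 0)
      .msg("isoform ", iso, " linked to phase set ", psh[1],
           " but no phase-set variant falls inside its exons")
    rows[[length(rows) + 1L]] <- data.frame(
      isoform_id = iso, phase_set = psh[1], haplotype = psh[2],
      n_tagged = length(tags), n_linked = as.integer(tab[1]),
      stringsAsFactors = FALSE)
    rows[[length(rows)]]$variants <- list(vsel)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(isoform_id = character(), phase_set = character(),
                      haplotype = character(), n_tagged = integer(),
                      n_linked = integer())
  out
}

#' Haplotype-specific transcript bias test
#'
#' For each variant of each gene with at least two isoforms covering it,
#' tests whether the allele balance in one isoform differs from the pooled
#' balance of the gene's other isoforms: a two-sided Fisher exact test on
#' `[[ref_iso, alt_iso], [ref_other, alt_other]]`, Benjamini-Hochberg
#' adjusted across all tests performed. Degenerate tables (a zero margin)
#' get p = 1 and are flagged.
#'
#' @param counts `data.frame` with columns `gene_id`, `isoform_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `ref_count`, `alt_count` (one row per variant x
#'   isoform; see [hst_counts_from_profiles()]).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @return `data.frame` with the Additional-file-style columns `chrom`,
#'   `pos`, `ref`, `alt`, `isoform_id`, `p_value`, `ref_count`, `alt_count`,
#'   `ref_other`, `alt_other`, plus `gene_id`, `adjusted_p` (BH),
#'   `degenerate` and `significant`.
#' @export
hst_bias_test <- function(counts, alpha = 0.05) {
  rows <- list()
  for (g in unique(counts$gene_id)) {
    cg <- counts[counts$gene_id == g, , drop = FALSE]
    for (key in unique(paste(cg$chrom, cg$pos, cg$ref, cg$alt))) {
      cv <- cg[paste(cg$chrom, cg$pos, cg$ref, cg$alt) == key, , drop = FALSE]
      covered <- cv$ref_count + cv$alt_count > 0
      if (sum(covered) < 2) next   # need >= 2 isoforms with reads
      for (i in which(covered)) {
        a <- cv$ref_count[i]; b <- cv$alt_count[i]
        cc <- sum(cv$ref_count[-i]); d <- sum(cv$alt_count[-i])
        ft <- fisher2x2(a, b, cc, d)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cv$chrom[i], pos = cv$pos[i], ref = cv$ref[i],
          alt = cv$alt[i], isoform_id = cv$isoform_id[i],
          p_value = ft$p, ref_count = a, alt_count = b,
          ref_other = cc, alt_other = d, gene_id = g,
          degenerate = ft$degenerate, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      isoform_id = character(), p_value = numeric(),
                      ref_count = integer(), alt_count = integer(),
                      ref_other = integer(), alt_other = integer(),
                      gene_id = character(), degenerate = logical(),
                      adjusted_p = numeric(), significant = logical()))
  out$adjusted_p <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$adjusted_p < alpha
  rownames(out) <- NULL
  out
}

#' Per-isoform allele counts from read profiles
#'
#' Convenience bridge from [profile_reads()] output to the count table
#' consumed by [hst_bias_test()].
#'
#' @param profiles List of profiles from [profile_reads()].
#' @param models Named list of [transcript_model()] (for gene ids).
#' @return `data.frame` with one row per isoform x variant.
#' @export
hst_counts_from_profiles <- function(profiles, models) {
  rows <- list()
  for (pr in profiles) {
    v <- pr$variants
    for (vi in seq_len(nrow(v))) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = models[[pr$isoform_id]]$gene_id,
        isoform_id = pr$isoform_id, chrom = v$chrom[vi], pos = v$pos[vi],
        ref = v$ref[vi], alt = v$alt[vi],
        ref_count = sum(pr$obs[, vi] == "ref"),
        alt_count = sum(pr$obs[, vi] == "alt"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), isoform_id = character(),
                      chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      ref_count = integer(), alt_count = integer())
  rownames(out) <- NULL
  out
}

#' Write haplotype-specific transcript outputs
#'
#' Emits, per haplotype group: the isoform sequence with alternate bases
#' substituted at the variants' transcript coordinates (complemented on
#' minus-strand isoforms), a BED12 row for the model, and a VCF of the
#' variants annotated with the isoforms carrying them (`ISO=` INFO key).
#'
#' @param haplotype_groups `data.frame` from [tabulate_all_haplotypes()].
#' @param models Named list of [transcript_model()].
#' @param variants `data.frame` of variants (as in [parse_vcf()]).
#' @param genome Named [Biostrings::DNAStringSet] or FASTA path.
#' @param out_prefix Path prefix; writes `<prefix>.fa`, `<prefix>.bed`,
#'   `<prefix>.vcf`.
#' @return Invisibly, a list with the HST [Biostrings::DNAStringSet] and the
#'   written paths.
#' @export
emit_hst_outputs <- function(haplotype_groups, models, variants, genome,
                             out_prefix) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  vkey <- paste0(variants$chrom, ":", variants$pos)
  seqs <- character(0)
  bed_models <- list()
  iso_of_variant <- setNames(vector("list", length(vkey)), vkey)

  for (i in seq_len(nrow(haplotype_groups))) {
    iso <- haplotype_groups$isoform_id[i]
    m <- models[[iso]]
    base_seq <- as.character(transcript_sequences(list(m), genome)[[1]])
    alleles <- haplotype_groups$alleles[[i]]
    hid <- paste0(iso, "_hap", i)
    for (site in names(alleles)[alleles == "alt"]) {
      vrow <- variants[match(site, vkey), ]
      t_off <- genome_to_tx(m, vrow$pos)
      if (is.na(t_off) || t_off + 1 > nchar(base_seq))
        stop("substitution position outside sequence for ", hid)
      sub_base <- if (m$strand == "-") .comp_base(vrow$alt) else vrow$alt
      substr(base_seq, t_off + 1, t_off + 1) <- sub_base
      iso_of_variant[[site]] <- unique(c(iso_of_variant[[site]], hid))
    }
    seqs[hid] <- base_seq
    bed_models[[hid]] <- transcript_model(hid, m$gene_id, m$chrom, m$strand,
                                          m$exons)
  }
  fa <- paste0(out_prefix, ".fa")
  bed <- paste0(out_prefix, ".bed")
  vcf <- paste0(out_prefix, ".vcf")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa)
  write_bed12(bed_models, bed)
  keep_keys <- names(iso_of_variant)[!vapply(iso_of_variant, is.null, TRUE)]
  v_used <- variants[vkey %in% keep_keys, , drop = FALSE]
  v_used$isoforms <- vapply(seq_len(nrow(v_used)), function(i)
    paste(iso_of_variant[[paste0(v_used$chrom[i], ":", v_used$pos[i])]],
          collapse = ","), "")
  write_vcf(v_used, vcf)
  invisible(list(sequences = Biostrings::DNAStringSet(seqs),
                 paths = c(fa = fa, bed = bed, vcf = vcf)))
}

#' Write the HST bias table (Additional-file-1 layout)
#'
#' Columns: chromosome, position, ref allele, alt allele, isoform, Fisher p,
#' ref/alt counts in the isoform, ref/alt counts in the gene's other
#' isoforms. A header comment records the BH adjustment.
#'
#' @param test_results `data.frame` from [hst_bias_test()].
#' @param path Output TSV path.
#' @export
write_hst_table <- function(test_results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# haplotype-specific transcript bias; p adjusted by ",
                    "Benjamini-Hochberg"), con)
  df <- test_results[, c("chrom", "pos", "ref", "alt", "isoform_id",
                         "p_value", "ref_count", "alt_count", "ref_other",
                         "alt_other")]
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
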