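#' Parse transcript models from GTF
#'
#' Reads exon features from one or more GTF files (Ensembl/GENCODE dialect)
#' and assembles one [transcript_model()] per transcript. GTF's 1-based closed
#' intervals are converted to the package's 0-based half-open convention.
#' Exon order is normalised to ascending genomic coordinates regardless of
#' strand or input order. Records without `transcript_id`/`gene_id` are
#' skipped with a warning; duplicate transcript ids across files are resolved
#' first-seen-wins (logged).
#'
#' @param paths Character vector of GTF file paths.
#' @return Named list of [transcript_model()] objects (names = transcript id).
#' @export
parse_gtf <- function(paths) {
  out <- list()
  for (path in paths) {
    gr <- rtracklayer::import(path, format = "gtf", feature.type = "exon")
    df <- as.data.frame(gr)
    if (is.null(df$transcript_id)) df$transcript_id <- NA_character_
    if (is.null(df$gene_id)) df$gene_id <- NA_character_
    bad <- is.na(df$transcript_id) | is.na(df$gene_id)
    if (any(bad)) {
      warning(sum(bad), " exon record(s) without transcript_id/gene_id ",
              "skipped in ", path)
      df <- df[!bad, , drop = FALSE]
    }
    for (tid in unique(df$transcript_id)) {
      if (!is.null(out[[tid]])) {
        .msg("duplicate transcript_id '", tid, "' ignored (first seen wins)")
        next
      }
      rec <- df[df$transcript_id == tid, , drop = FALSE]
      out[[tid]] <- transcript_model(
        transcript_id = tid,
        gene_id = rec$gene_id[1],
        chrom = as.character(rec$seqnames[1]),
        strand = as.character(rec$strand[1]),
        exons = cbind(rec$start - 1L, rec$end))   # GTF 1-closed -> 0-half-open
    }
  }
  if (length(out) == 0) stop("no transcript models parsed from: ",
                             paste(paths, collapse = ", "))
  out
}

#' Write transcript models as BED12
#'
#' One line per model; name field encodes `transcriptid_geneid` (split on the
#' last underscore when reading back), blockStarts relative to chromStart.
#' Round-trips losslessly through [parse_bed12()].
#'
#' @param models List of [transcript_model()].
#' @param path Output file.
#' @param scores Optional numeric vector (defaults to 0).
#' @export
write_bed12 <- function(models, path, scores = NULL) {
  if (length(models) == 0) {
    file.create(path)
    return(invisible(path))
  }
  if (is.null(scores)) scores <- rep(0L, length(models))
  rows <- mapply(function(m, sc) {
    ex <- m$exons
    cs <- ex[1, 1]
    ce <- ex[nrow(ex), 2]
    c(m$chrom, cs, ce, paste0(m$transcript_id, "_", m$gene_id), sc,
      m$strand, cs, ce, "0", nrow(ex),
      paste(ex[, 2] - ex[, 1], collapse = ","),
      paste(ex[, 1] - cs, collapse = ","))
  }, models, scores)
  write.table(t(rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parse BED12 into transcript models
#'
#' Inverse of [write_bed12()]: the name field's last underscore separates
#' transcript id from gene id (a name without an underscore yields
#' `gene_id = NA`).
#'
#' @param path BED12 file.
#' @return Named list of [transcript_model()].
#' @export
parse_bed12 <- function(path) {
  if (file.size(path) == 0) return(list())
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("not BED12: ", path)
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    cs <- df[i, 2]
    sizes <- as.integer(strsplit(as.character(df[i, 11]), ",")[[1]])
    starts <- as.integer(strsplit(as.character(df[i, 12]), ",")[[1]])
    name <- df[i, 4]
    us <- regexpr("_[^_]*$", name)
    tid <- if (us > 0) substr(name, 1, us - 1) else name
    gid <- if (us > 0) substr(name, us + 1, nchar(name)) else NA_character_
    out[[i]] <- transcript_model(tid, gid, df[i, 1], df[i, 6],
                                 cbind(cs + starts, cs + starts + sizes))
  }
  names(out) <- vapply(out, `[[`, "", "transcript_id")
  out
}

#' Parse SNVs from VCF files
#'
#' Reads one or more VCF 4.x files (plain or bgzipped), keeps biallelic SNV
#' records (splitting multi-allelic ALTs), converts POS to 0-based, and
#' returns the de-duplicated union over files keyed on (chrom, pos, ref, alt).
#' Non-SNV records are dropped and counted. A per-sample `PS` FORMAT field,
#' when present, is carried as the phase-set label of the variant.
#'
#' @param paths Character vector of VCF paths.
#' @return `data.frame` with columns `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `phase_set` (character or `NA`).
#' @export
parse_vcf <- function(paths) {
  acc <- list()
  dropped <- 0L
  for (path in paths) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    ps <- rep(NA_character_, nrow(fix))
    if (!is.null(v@gt) && ncol(v@gt) >= 2 &&
        any(grepl("PS", v@gt[, 1], fixed = TRUE))) {
      psm <- tryCatch(vcfR::extract.gt(v, element = "PS"),
                      error = function(e) NULL)
      if (!is.null(psm)) ps <- as.character(psm[, 1])
    }
    for (i in seq_len(nrow(fix))) {
      pos1 <- suppressWarnings(as.integer(fix[i, "POS"]))
      ref <- fix[i, "REF"]
      if (is.na(pos1) || is.na(ref))
        stop("malformed VCF record ", i, " in ", path)
      alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
      for (alt in alts) {
        if (nchar(ref) != 1 || nchar(alt) != 1 ||
            !ref %in% c("A", "C", "G", "T") ||
            !alt %in% c("A", "C", "G", "T") || ref == alt) {
          dropped <- dropped + 1L
          next
        }
        key <- paste(fix[i, "CHROM"], pos1 - 1L, ref, alt, sep = ":")
        if (is.null(acc[[key]]))
          acc[[key]] <- data.frame(chrom = fix[i, "CHROM"], pos = pos1 - 1L,
                                   ref = ref, alt = alt, phase_set = ps[i],
                                   stringsAsFactors = FALSE)
      }
    }
  }
  if (dropped > 0) .msg(dropped, " non-SNV allele record(s) dropped")
  if (length(acc) == 0)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), phase_set = character()))
  out <- do.call(rbind, acc)
  rownames(out) <- NULL
  out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
}

#' Write variants as a minimal VCF
#'
#' @param variants `data.frame` as returned by [parse_vcf()]; an optional
#'   `isoforms` character column is written as an `ISO=` INFO key (the
#'   isoform ids carrying the variant).
#' @param path Output path.
#' @export
write_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=ISO,Number=.,Type=String,Description=\"Isoforms carrying this variant\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants) > 0) {
    info <- if (!is.null(variants$isoforms))
      paste0("ISO=", variants$isoforms) else "."
    writeLines(paste(variants$chrom, variants$pos + 1L, ".", variants$ref,
                     variants$alt, ".", ".", info, sep = "\t"), con)
  }
  invisible(path)
}

#' Spliced transcript sequences from a genome
#'
#' Concatenates exon sequences 5'->3' in transcript orientation
#' (reverse-complemented for minus-strand models).
#'
#' @param models List of [transcript_model()].
#' @param genome A named [Biostrings::DNAStringSet] or path to a FASTA file.
#' @return [Biostrings::DNAStringSet] named by transcript id.
#' @export
transcript_sequences <- function(models, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  seqs <- vapply(models, function(m) {
    if (!m$chrom %in% names(genome))
      stop("chromosome '", m$chrom, "' absent from genome FASTA")
    chr <- genome[[m$chrom]]
    s <- paste(vapply(seq_len(nrow(m$exons)), function(i)
      as.character(Biostrings::subseq(chr, m$exons[i, 1] + 1L, m$exons[i, 2])),
      ""), collapse = "")
    if (m$strand == "-") .revcomp(s) else s
  }, "")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- vapply(models, `[[`, "", "transcript_id")
  out
}
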