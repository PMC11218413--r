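# Independent oracles used across the suite. Each recomputes a quantity by a
# different route than the implementation (explicit enumeration, per-base
# walks, all-pairs scans) on problem sizes where brute force is exact.

# Two-sided Fisher p by exhaustive hypergeometric enumeration with explicit
# binomial coefficients (choose products, no dhyper). Ties handled with the
# same relative tolerance convention as the exact conditional test.
fisher_enum_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  lo <- max(0, r1 + c1 - N)
  hi <- min(r1, c1)
  xs <- lo:hi
  prob <- vapply(xs, function(x)
    choose(r1, x) * choose(N - r1, c1 - x), 0) / choose(N, c1)
  pobs <- prob[a - lo + 1]
  min(1, sum(prob[prob <= pobs * (1 + 1e-7)]))
}

# Fidelity metrics by a per-base walk: build the per-target-position status
# vector and score windows position by position.
fidelity_walk_oracle <- function(aln, model, end_window = 25L) {
  L <- hapiso::tx_length(model)
  status <- rep(NA_character_, L)       # 1-indexed by target pos + 1
  indels <- list()
  t <- aln$target_start
  matched <- 0L; mism <- 0L; ins <- 0L
  for (i in seq_len(nrow(aln$ops))) {
    op <- aln$ops$op[i]; len <- aln$ops$len[i]
    if (op == "match") {
      for (k in seq_len(len)) status[t + k] <- "match"
      matched <- matched + len; t <- t + len
    } else if (op == "mismatch") {
      for (k in seq_len(len)) status[t + k] <- "mismatch"
      mism <- mism + len; t <- t + len
    } else if (op == "insertion") {
      ins <- ins + len
      indels[[length(indels) + 1L]] <- c(t, t, len)
    } else if (op == "deletion") {
      for (k in seq_len(len)) status[t + k] <- "deletion"
      indels[[length(indels) + 1L]] <- c(t, t + len, len)
      t <- t + len
    } else stop("unexpected op")
  }
  t_end <- t
  # junction offsets in transcript orientation
  lens <- model$exons[, 2] - model$exons[, 1]
  cs <- cumsum(lens)[-length(lens)]
  if (length(lens) == 1) cs <- integer(0)
  joff <- if (model$strand == "+") cs else sort(sum(lens) - cs)
  flank <- rep(NA_integer_, length(joff))
  maxind <- rep(0L, length(joff))
  for (k in seq_along(joff)) {
    w <- (joff[k] - 3L):(joff[k] + 2L)      # the six flanking positions
    if (any(w < aln$target_start) || any(w >= t_end)) next
    flank[k] <- sum(vapply(w, function(p)
      identical(status[p + 1], "match"), TRUE))
    for (iv in indels) {
      touches <- if (iv[1] == iv[2]) iv[1] >= joff[k] - 3L &&
        iv[1] <= joff[k] + 3L
      else iv[1] < joff[k] + 3L && iv[2] > joff[k] - 3L
      if (touches) maxind[k] <- max(maxind[k], iv[3])
    }
  }
  aligned <- matched + mism + ins
  list(match_fraction = if (aligned) matched / aligned else 0,
       covers_first_exon = aln$target_start <= end_window,
       covers_last_exon = (L - t_end) <= end_window,
       junction_flank_matches = flank,
       junction_max_indel = maxind)
}

# Type II hyperediting regions by full scan: every site-anchored window is
# scored by scanning all sites; qualifying spans merged by repeated sweeps.
type2_oracle <- function(pos, window = 150L, min_sites = 3L) {
  p <- sort(unique(pos))
  spans <- NULL
  for (s in p) {
    cnt <- sum(p >= s & p < s + window)
    if (cnt >= min_sites) spans <- rbind(spans, c(s, s + window))
  }
  if (is.null(spans)) return(NULL)
  # naive merge: iterate until stable
  repeat {
    merged <- FALSE
    i <- 1
    while (i < nrow(spans)) {
      j <- i + 1
      while (j <= nrow(spans)) {
        if (spans[i, 1] <= spans[j, 2] && spans[j, 1] <= spans[i, 2]) {
          spans[i, ] <- c(min(spans[i, 1], spans[j, 1]),
                          max(spans[i, 2], spans[j, 2]))
          spans <- spans[-j, , drop = FALSE]
          merged <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  t(apply(spans, 1, function(sp) {
    inside <- p[p >= sp[1] & p < sp[2]]
    c(start = min(inside), end = max(inside), n = length(inside))
  }))
}

# Single-linkage 1-d clustering by brute force on the pairwise graph.
single_linkage_oracle <- function(x, window) {
  n <- length(x)
  comp <- seq_len(n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (abs(x[i] - x[j]) <= window) comp[comp == comp[j]] <- comp[i]
  match(comp, unique(comp))
}

# Random op-list generator for fidelity property tests (transcript space).
random_tx_alignment <- function(model, read_id = "r1") {
  L <- hapiso::tx_length(model)
  t0 <- sample(0:min(30, L - 20), 1)
  t1 <- L - sample(0:min(30, L - t0 - 10), 1)
  ops <- list()
  remaining <- t1 - t0
  while (remaining > 0) {
    op <- sample(c("match", "mismatch", "insertion", "deletion"), 1,
                 prob = c(0.7, 0.1, 0.1, 0.1))
    len <- sample(1:min(8, max(1, remaining)), 1)
    if (op %in% c("match", "mismatch", "deletion")) {
      len <- min(len, remaining)
      remaining <- remaining - len
    }
    ops[[length(ops) + 1L]] <- data.frame(op = op, len = len)
  }
  if (length(ops) == 0) ops[[1]] <- data.frame(op = "match", len = 1)
  hapiso::read_alignment(read_id, model$transcript_id, "transcript",
                         target_start = t0, ops = do.call(rbind, ops))
}

# Random non-overlapping exon structure.
random_model <- function(n_ex, id = "t1", gene = "g1", chrom = "chr1",
                         strand = NULL, exon_len = 30:200, gap = 50:300) {
  lens <- sample(exon_len, n_ex, replace = TRUE)
  gaps <- sample(gap, n_ex, replace = TRUE)
  starts <- cumsum(gaps + c(0L, lens[-n_ex]))
  if (is.null(strand)) strand <- sample(c("+", "-"), 1)
  hapiso::transcript_model(id, gene, chrom, strand,
                           cbind(starts, starts + lens))
}

# FIX row of a (possibly single-record) vcfR object, with INFO.
vcf_fix1 <- function(v) {
  x <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(x))) x else x[1, ]
}

# Tiny deterministic transcript model helper.
toy_model <- function(exons, strand = "+", id = "tx1", gene = "g1",
                      chrom = "chr1") {
  hapiso::transcript_model(id, gene, chrom, strand, exons)
}

# Build a simple ungapped alignment (single block of ops) helper.
mk_aln <- function(ops, start = 0L, id = "r1", target = "tx1",
                   kind = "transcript", seq = NULL, mapq = 60L,
                   strand = "+", tags = list()) {
  hapiso::read_alignment(id, target, kind, start,
                         data.frame(op = names(ops), len = unname(ops)),
                         mapq = mapq, seq = seq, strand = strand, tags = tags)
}
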