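#' @noRd
.msg <- function(...) message("hapiso: ", ...)

#' FNV-1a hash of a string, as 8 hex digits
#'
#' Used to derive stable novel-isoform identifiers from junction chains.
#' Pure integer arithmetic (via doubles below 2^53), platform independent.
#' @noRd
.fnv1a <- function(x) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(x)) {
    # xor only touches the low byte since b < 256
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    # 32-bit modular multiply without exceeding 2^53
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  # h is a double below 2^32; render hex without 32-bit coercion overflow
  hi <- floor(h / 65536)
  sprintf("%04x%04x", as.integer(hi), as.integer(h - hi * 65536))
}

#' Complement of single bases (character vector)
#' @noRd
.comp_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])
}

#' Reverse complement of a plain character string
#' @noRd
.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Local RNG seeding helper: derive a sub-seed from a base seed and an offset,
#' keeping the result in 32-bit integer range.
#' @noRd
.subseed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% .Machine$integer.max)
}
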