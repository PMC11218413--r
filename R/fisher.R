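#' Two-sided Fisher exact test on a 2x2 table
#'
#' Shared test core for haplotype bias, differential editing and co-editing.
#' Wraps [stats::fisher.test()] with the package-wide degenerate-table
#' convention: any zero margin yields p = 1 (no information), flagged.
#'
#' @param a,b,c,d Cell counts, row-wise: `[[a, b], [c, d]]`.
#' @return List with `p` (two-sided p-value) and `degenerate` (logical,
#'   TRUE when a margin was zero).
#' @export
fisher2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    return(list(p = 1, degenerate = TRUE))
  p <- stats::fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
  list(p = min(p, 1), degenerate = FALSE)
}
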