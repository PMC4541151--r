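# Pairwise protein alignment primitives used by the progressive MSA and the
# candidate-to-reference mapping.

.check_protein <- function(x, what = "sequence") {
  if (!nzchar(x)) .stopf("empty %s", what)
  ok <- c(.aa_alphabet(), "X")
  pos <- regexpr(sprintf("[^%s]", paste(ok, collapse = "")), x)
  if (pos > 0L)
    .stopf("invalid residue '%s' in %s at position %d",
           substr(x, pos, pos), what, pos)
  invisible(x)
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch/Gotoh alignment with affine gaps (a gap of length L costs
#' `gapOpen + L * gapExtend`) under BLOSUM62. Traceback is deterministic:
#' diagonal preferred, then up (gap in `b`), then left (gap in `a`).
#'
#' @param a,b Protein sequences over the 20-letter alphabet plus X.
#' @param gapOpen,gapExtend Gap penalties (defaults 10 and 1).
#' @param substitution Substitution matrix name; only "BLOSUM62" ships.
#' @return List with `score` and `alignment` (character vector of the two
#'   gapped rows).
#' @export
globalAlignPair <- function(a, b, gapOpen = 10, gapExtend = 1,
                            substitution = "BLOSUM62") {
  stopifnot(identical(substitution, "BLOSUM62"))
  a <- toupper(a); b <- toupper(b)
  .check_protein(a, "first sequence")
  .check_protein(b, "second sequence")
  B <- .blosum62()
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  S <- B[av, bv, drop = FALSE]
  res <- .C_nw_affine(S, gapOpen, gapExtend)
  ga <- ifelse(res$path_a == 0L, "-", av[pmax(res$path_a, 1L)])
  gb <- ifelse(res$path_b == 0L, "-", bv[pmax(res$path_b, 1L)])
  list(score = res$score,
       alignment = c(paste(ga, collapse = ""), paste(gb, collapse = "")))
}

#' Percent identity of an aligned pair
#'
#' 100 times the number of identical co-ungapped column pairs over the number
#' of columns where both rows carry a residue; 0 (with a warning) when the
#' rows never overlap.
#'
#' @param pair Character vector of two equal-length gapped rows, or the list
#'   returned by [globalAlignPair()].
#' @return Percent identity in \[0, 100\].
#' @export
percentIdentity <- function(pair) {
  if (is.list(pair)) pair <- pair$alignment
  if (length(pair) != 2L) .stopf("need exactly two aligned rows")
  if (nchar(pair[1L]) != nchar(pair[2L]))
    .stopf("aligned rows differ in length (%d vs %d)",
           nchar(pair[1L]), nchar(pair[2L]))
  a <- strsplit(pair[1L], "", fixed = TRUE)[[1L]]
  b <- strsplit(pair[2L], "", fixed = TRUE)[[1L]]
  both <- a != "-" & b != "-"
  if (!any(both)) {
    .warnf("aligned rows share no co-ungapped column; identity reported as 0")
    return(0)
  }
  100 * sum(a[both] == b[both]) / sum(both)
}
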