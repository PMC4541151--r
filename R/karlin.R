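# Karlin-Altschul statistics for ungapped local alignment under uniform base
# frequencies. E = m * n * 2^(-bitscore) with bitscore = (lambda*S - ln K)/ln 2.

# published ungapped (lambda, K) calibrations for canonical blastn score
# pairs, keyed by "match/mismatch" after division by gcd; K is scale-invariant
# so e.g. (2,-4) resolves to the (1,-2) entry
.KA_KAPPA <- c("1/-2" = 0.621, "1/-3" = 0.711, "1/-4" = 0.738)

.gcd2 <- function(a, b) if (b == 0L) a else .gcd2(b, a %% b)

#' Solve the Karlin-Altschul identity for a match/mismatch scoring scheme
#'
#' Finds the unique positive root lambda of
#' \eqn{\sum_{ij} p_i p_j e^{\lambda s(i,j)} = 1} with uniform
#' \eqn{p_i = 1/4}, i.e. \eqn{\frac14 e^{\lambda\,match} + \frac34
#' e^{\lambda\,mismatch} = 1}. The scheme is valid only when the expected
#' pair score is negative. kappa comes from a fixed lookup of published
#' ungapped calibrations for canonical score pairs (reduced by their gcd;
#' kappa is invariant under score scaling while lambda scales inversely);
#' `NA` is returned for pairs without a calibrated entry, in which case
#' [searchParams()] requires an explicit `kappa`.
#'
#' @param match Positive integer match score.
#' @param mismatch Negative integer mismatch score.
#' @return List with elements `lambda` (nats) and `kappa` (possibly `NA`).
#' @export
solveKarlinAltschul <- function(match = 1L, mismatch = -2L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  if (!(match > 0L && mismatch < 0L))
    .stopf("invalid scoring scheme: need match > 0 > mismatch")
  p <- 0.25
  expected <- p * match + (1 - p) * mismatch
  if (expected >= 0)
    .stopf("invalid scoring scheme: expected pair score %.3f is not negative",
           expected)
  f <- function(l) p * exp(l * match) + (1 - p) * exp(l * mismatch) - 1
  # f(0) = 0 is a trivial root; the positive root exists since f'(0) < 0 and
  # f -> Inf. Bracket above a point where f is still negative.
  hi <- 1 / match
  while (f(hi) < 0) hi <- hi * 2
  lambda <- uniroot(f, lower = 1e-12, upper = hi, tol = 1e-14)$root
  g <- .gcd2(match, -mismatch)
  key <- sprintf("%d/%d", match %/% g, mismatch %/% g)
  kappa <- if (key %in% names(.KA_KAPPA)) unname(.KA_KAPPA[[key]]) else NA_real_
  list(lambda = lambda, kappa = kappa)
}

#' Construct search parameters
#'
#' Builds a [SearchParams] object for the seeded local nucleotide search.
#' Defaults mirror legacy blastn (+1/-2, gap open 5, gap extend 2, word 11)
#' with the screening cutoffs used for reference-gene recovery: alignment
#' length >= 40 bp and E-value <= 1e-4. E-values apply the ungapped
#' Karlin-Altschul pair to gapped scores (a documented approximation; only
#' the cutoff decision matters downstream).
#'
#' @param wordSize Seed word length (>= 4).
#' @param match,mismatch Match/mismatch scores.
#' @param gapOpen,gapExtend Affine gap penalties (gap of length L costs
#'   gapOpen + L*gapExtend).
#' @param maxEvalue E-value cutoff applied by [filterHits()].
#' @param minAlignLen Alignment-length cutoff in bp applied by [filterHits()]
#'   (threshold-inclusive: hits of exactly this length are kept).
#' @param minIdentityPct Identity cutoff in percent (0 = off at search stage).
#' @param kappa Override for Karlin-Altschul K (required for score pairs
#'   without a calibrated lookup entry).
#' @param xDrop X-drop for the ungapped seed extension, raw score units.
#' @return A validated [SearchParams].
#' @export
searchParams <- function(wordSize = 11L, match = 1L, mismatch = -2L,
                         gapOpen = 5L, gapExtend = 2L,
                         maxEvalue = 1e-4, minAlignLen = 40L,
                         minIdentityPct = 0, kappa = NULL, xDrop = 20) {
  ka <- solveKarlinAltschul(match, mismatch)
  if (!is.null(kappa)) ka$kappa <- kappa
  if (is.na(ka$kappa))
    .stopf(paste0("no calibrated kappa for score pair (%d, %d); ",
                  "supply kappa= explicitly"), match, mismatch)
  new("SearchParams",
      wordSize = as.integer(wordSize), match = as.integer(match),
      mismatch = as.integer(mismatch), gapOpen = as.integer(gapOpen),
      gapExtend = as.integer(gapExtend), lambda = ka$lambda,
      kappa = ka$kappa, maxEvalue = maxEvalue,
      minAlignLen = as.integer(minAlignLen),
      minIdentityPct = minIdentityPct, xDrop = xDrop)
}

#' Bit score and E-value from a raw alignment score
#'
#' @param rawScore Raw alignment score(s).
#' @param m Query (contig) length.
#' @param n Total database length.
#' @param params A [SearchParams].
#' @return data.frame with `bit_score` and `evalue`.
#' @export
scoreToEvalue <- function(rawScore, m, n, params) {
  bit <- (params@lambda * rawScore - log(params@kappa)) / log(2)
  data.frame(bit_score = bit,
             evalue = as.numeric(m) * as.numeric(n) * 2^(-bit))
}
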