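# Progressive protein multiple alignment: NJ guide tree on pairwise-identity
# distances, profile-profile merges up the tree with position-specific
# sum-of-pairs scoring (expected BLOSUM62 score between column residue
# frequency profiles; gaps contribute zero).

.profile_freqs <- function(rows) {
  alph <- c(.aa_alphabet(), "X")
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  FA <- matrix(0, length(alph), ncol(m), dimnames = list(alph, NULL))
  for (a in alph) FA[a, ] <- colMeans(m == a)
  FA
}

.merge_profiles <- function(A, B, gapOpen, gapExtend) {
  # A, B: lists with names, rows
  alph <- c(.aa_alphabet(), "X")
  S <- t(.profile_freqs(A$rows)) %*% .blosum62()[alph, alph] %*%
    .profile_freqs(B$rows)
  res <- .C_nw_affine(S, gapOpen, gapExtend)
  na <- length(A$rows); nb <- length(B$rows)
  splitA <- strsplit(A$rows, "", fixed = TRUE)
  splitB <- strsplit(B$rows, "", fixed = TRUE)
  ncolo <- length(res$path_a)
  outA <- matrix("-", na, ncolo)
  outB <- matrix("-", nb, ncolo)
  ia <- res$path_a > 0L
  ib <- res$path_b > 0L
  for (r in seq_len(na)) outA[r, ia] <- splitA[[r]][res$path_a[ia]]
  for (r in seq_len(nb)) outB[r, ib] <- splitB[[r]][res$path_b[ib]]
  list(names = c(A$names, B$names),
       rows = c(apply(outA, 1L, paste, collapse = ""),
                apply(outB, 1L, paste, collapse = "")))
}

#' Progressive multiple alignment of protein sequences
#'
#' Builds an NJ guide tree from pairwise-identity distances
#' (d = 1 - pid/100), then merges profiles post-order up the midpoint-rooted
#' guide tree. Two sequences reduce exactly to [globalAlignPair()]. Row order
#' of the result follows the input.
#'
#' @param seqs Named character vector of at least two protein sequences.
#' @param gapOpen,gapExtend Affine gap penalties (defaults 10, 1).
#' @return A [ProteinMSA]; ungapping any row reproduces its input sequence.
#' @export
progressiveMsa <- function(seqs, gapOpen = 10, gapExtend = 1) {
  if (is.list(seqs)) seqs <- unlist(seqs)
  n <- length(seqs)
  if (n < 2L) .stopf("nothing to align: need at least 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    .stopf("sequences must carry unique names")
  for (i in seq_len(n)) .check_protein(seqs[[i]], names(seqs)[i])
  if (n == 2L) {
    aln <- globalAlignPair(seqs[[1L]], seqs[[2L]], gapOpen, gapExtend)
    return(new("ProteinMSA", names = names(seqs), rows = aln$alignment))
  }
  D <- identityDistances(seqs, gapOpen, gapExtend)
  guide <- phangorn::midpoint(njTree(D))
  merged <- .align_node(guide, length(guide$tip.label) + 1L, seqs,
                        gapOpen, gapExtend)
  o <- match(names(seqs), merged$names)
  new("ProteinMSA", names = names(seqs), rows = merged$rows[o])
}

# recursive post-order profile merge at a node of the rooted guide tree
.align_node <- function(tree, node, seqs, gapOpen, gapExtend) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) {
    nm <- tree$tip.label[node]
    return(list(names = nm, rows = unname(seqs[[nm]])))
  }
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  sub <- lapply(kids, .align_node, tree = tree, seqs = seqs,
                gapOpen = gapOpen, gapExtend = gapExtend)
  acc <- sub[[1L]]
  for (k in seq_along(sub)[-1L])
    acc <- .merge_profiles(acc, sub[[k]], gapOpen, gapExtend)
  acc
}

#' Trim a protein alignment to its conserved blocks
#'
#' Columns are classified conserved when their most frequent non-gap residue
#' reaches `consFrac` of the rows (strict when it reaches `strictFrac`) and
#' the gap fraction is at most `maxGapFrac`. Gap-heavy columns and maximal
#' runs of more than `maxNonconsRun` consecutive non-conserved columns break
#' blocks; surviving blocks are shrunk to start and end on strict columns and
#' dropped when shorter than `minBlockLen`. The trimmed alignment is the
#' concatenation of the kept blocks.
#'
#' @param msa A [ProteinMSA] with at least 2 rows.
#' @param minBlockLen Minimum kept block length (columns), default 10.
#' @param maxNonconsRun Longest tolerated run of non-conserved columns inside
#'   a block, default 8.
#' @param consFrac Conserved-column majority fraction, default 0.5.
#' @param strictFrac Strict (flank) majority fraction, default 0.85.
#' @param maxGapFrac Maximum per-column gap fraction, default 0.5.
#' @return List with `blocks` (data.frame of kept \[start, end) column
#'   intervals, 0-based), `msa` (trimmed [ProteinMSA]; zero-width when no
#'   block survives, with a warning) and `params`.
#' @export
trimConservedBlocks <- function(msa, minBlockLen = 10L, maxNonconsRun = 8L,
                                consFrac = 0.5, strictFrac = 0.85,
                                maxGapFrac = 0.5) {
  stopifnot(is(msa, "ProteinMSA"), length(msa) >= 2L)
  m <- as.matrix(msa)
  nr <- nrow(m)
  gapfrac <- colMeans(m == "-")
  topfrac <- apply(m, 2L, function(col) {
    col <- col[col != "-"]
    if (!length(col)) 0 else max(table(col)) / nr
  })
  conserved <- topfrac >= consFrac & gapfrac <= maxGapFrac
  strict <- topfrac >= strictFrac & gapfrac <= maxGapFrac
  breaker <- gapfrac > maxGapFrac
  r <- rle(!conserved)
  pos <- cumsum(c(1L, r$lengths))
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && r$lengths[i] > maxNonconsRun)
      breaker[pos[i]:(pos[i + 1L] - 1L)] <- TRUE
  }
  runs <- rle(!breaker)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  blocks <- NULL
  for (i in seq_along(runs$lengths)) {
    if (!runs$values[i]) next
    s <- starts[i]; e <- ends[i]
    while (s <= e && !strict[s]) s <- s + 1L
    while (e >= s && !strict[e]) e <- e - 1L
    if (s > e || e - s + 1L < minBlockLen) next
    blocks <- rbind(blocks, c(s - 1L, e)) # 0-based half-open
  }
  if (is.null(blocks)) {
    .warnf("no conserved block survives trimming")
    blocks <- data.frame(start = integer(), end = integer())
    trimmed <- new("ProteinMSA", names = msa@names,
                   rows = rep("", length(msa@rows)))
  } else {
    blocks <- data.frame(start = blocks[, 1L], end = blocks[, 2L])
    keep <- unlist(mapply(function(s, e) (s + 1L):e, blocks$start,
                          blocks$end, SIMPLIFY = FALSE))
    trimmed <- new("ProteinMSA", names = msa@names,
                   rows = unname(apply(m[, keep, drop = FALSE], 1L, paste,
                                       collapse = "")))
  }
  list(blocks = blocks, msa = trimmed,
       params = list(minBlockLen = minBlockLen,
                     maxNonconsRun = maxNonconsRun, consFrac = consFrac,
                     strictFrac = strictFrac, maxGapFrac = maxGapFrac))
}
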