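# Neighbor-joining trees and Robinson-Foulds congruence. Tree containers are
# ape "phylo" objects throughout; newick serialization via ape.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via [ape::nj()]) with two
#' determinism/sanity post-passes: taxa are ordered lexicographically before
#' agglomeration so ties resolve reproducibly, and negative branch lengths
#' are clamped to zero with the deficit moved to the sister branch (pairwise
#' path lengths through the parent are preserved).
#'
#' @param D Symmetric distance matrix (or `dist`) with taxon names; zero
#'   diagonal; at least 3 taxa; no NA/NaN.
#' @return An unrooted `phylo` tree.
#' @export
njTree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (is.null(rownames(D))) .stopf("distance matrix must carry taxon names")
  if (nrow(D) < 3L) .stopf("need at least 3 taxa (got %d)", nrow(D))
  if (any(is.na(D)) || any(is.nan(D))) .stopf("NA/NaN in distance matrix")
  if (max(abs(D - t(D))) > 1e-8) .stopf("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-12)) .stopf("distance matrix diagonal must be 0")
  o <- order(rownames(D))
  D <- D[o, o, drop = FALSE]
  tr <- ape::nj(as.dist(D))
  # clamp negative branch lengths, moving the deficit to the sister edge
  repeat {
    neg <- which(tr$edge.length < -1e-12)
    if (!length(neg)) break
    e <- neg[which.min(tr$edge.length[neg])]
    parent <- tr$edge[e, 1L]
    sibs <- which(tr$edge[, 1L] == parent)
    sibs <- setdiff(sibs, e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs))
      tr$edge.length[sibs[1L]] <- tr$edge.length[sibs[1L]] + deficit
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# non-trivial bipartitions of an unrooted tree as canonical strings
.tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  if (is.null(labs)) labs <- tree$tip.label
  anchor <- min(labs)
  out <- character(0)
  for (cl in pp) {
    side <- labs[cl]
    if (!(anchor %in% side)) side <- setdiff(labs, side)
    if (length(side) <= 1L || length(side) >= n - 1L) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the non-trivial bipartition sets (only resolved
#' splits are counted for multifurcating trees), plus the normalization
#' rf / (2 (n - 3)) for n leaves.
#'
#' @param t1,t2 `phylo` trees on identical leaf label sets.
#' @return List with integer `rf` and `normalized` in \[0, 1\].
#' @export
robinsonFoulds <- function(t1, t2) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    d <- c(setdiff(l1, l2), setdiff(l2, l1))
    .stopf("leaf sets differ: %s", paste(d, collapse = ", "))
  }
  s1 <- .tree_splits(t1)
  s2 <- .tree_splits(t2)
  rf <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  n <- length(l1)
  norm <- if (n > 3L) rf / (2 * (n - 3L)) else 0
  list(rf = as.integer(rf), normalized = norm)
}

#' Pairwise identity distance matrix for a set of proteins
#'
#' Distances are 1 - pid/100 from global pairwise alignments (no
#' correction); used as the guide-tree and display-tree distance.
#'
#' @param seqs Named character vector of protein sequences.
#' @param gapOpen,gapExtend Gap penalties passed to [globalAlignPair()].
#' @return Symmetric matrix of distances with zero diagonal.
#' @export
identityDistances <- function(seqs, gapOpen = 10, gapExtend = 1) {
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pid <- percentIdentity(globalAlignPair(seqs[[i]], seqs[[j]],
                                             gapOpen, gapExtend))
      D[i, j] <- D[j, i] <- 1 - pid / 100
    }
  }
  D
}
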