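# Classic evolutionary-trace analysis: partition the reference tree into k
# groups by cutting its earliest-diverging nodes, rank alignment columns by
# the smallest k at which every group is internally invariant, and extract
# class-specific conserved columns and motif windows.

# ensure a rooted binary-ish tree for node ordering; midpoint-root if needed
.rooted_for_trace <- function(tree) {
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  tree
}

# leaves under each node, and topological depth (edges from root)
.node_info <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  kids <- vector("list", nnode)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1L]]] <- c(kids[[tree$edge[e, 1L]]], tree$edge[e, 2L])
  depth <- integer(nnode)
  leaves <- vector("list", nnode)
  root <- ntip + 1L
  order_nodes <- rev(ape::reorder.phylo(tree, "postorder")$edge[, 2L])
  depth[root] <- 0L
  for (nd in order_nodes) {
    par <- tree$edge[tree$edge[, 2L] == nd, 1L]
    depth[nd] <- depth[par] + 1L
  }
  post <- ape::reorder.phylo(tree, "postorder")$edge[, 2L]
  for (nd in seq_len(ntip)) leaves[[nd]] <- tree$tip.label[nd]
  for (nd in post) {
    if (nd > ntip)
      leaves[[nd]] <- unlist(lapply(kids[[nd]], function(k) leaves[[k]]))
  }
  leaves[[root]] <- tree$tip.label
  list(kids = kids, depth = depth, leaves = leaves, root = root,
       ntip = ntip)
}

#' Partition tree leaves into k monophyletic trace groups
#'
#' The tree is rooted (midpoint if unrooted) and its internal nodes ordered
#' by increasing topological depth from the root (earliest-diverging first);
#' cutting the top k-1 nodes yields k monophyletic groups. Ties in depth are
#' broken by the lexicographically smallest leaf contained under the node.
#'
#' @param tree A `phylo` tree.
#' @param k Number of groups, between 1 and the number of leaves.
#' @return A [TracePartition].
#' @export
partitionTree <- function(tree, k) {
  k <- as.integer(k)
  tree <- .rooted_for_trace(tree)
  info <- .node_info(tree)
  n <- info$ntip
  if (k < 1L || k > n) .stopf("k must be in [1, %d] (got %d)", n, k)
  frontier <- info$root
  while (length(frontier) < k) {
    internal <- frontier[frontier > n]
    # frontier always holds an internal node while length(frontier) < n
    minleaf <- vapply(internal, function(nd) min(info$leaves[[nd]]), "")
    pick <- internal[order(info$depth[internal], minleaf)][1L]
    frontier <- c(setdiff(frontier, pick), info$kids[[pick]])
  }
  groups <- lapply(frontier, function(nd) sort(info$leaves[[nd]]))
  groups <- groups[order(vapply(groups, min, ""))]
  new("TracePartition", k = k, groups = groups)
}

#' Partition groups
#' @param partition A [TracePartition].
#' @return List of leaf-name character vectors.
#' @export
partitionGroups <- function(partition) partition@groups

# is every listed group invariant at every column? returns logical per column
.groups_invariant <- function(m, groups) {
  ok <- rep(TRUE, ncol(m))
  for (g in groups) {
    rows <- m[g, , drop = FALSE]
    if (nrow(rows) <= 1L) next
    same <- colSums(rows != rows[rep(1L, nrow(rows)), , drop = FALSE]) == 0L
    ok <- ok & same
  }
  ok
}

#' Evolutionary-trace ranks of alignment columns
#'
#' For each column the rank is the smallest k (up to `maxRank`) such that
#' within every group of [partitionTree()] at that k all residues are
#' identical; gaps count as a distinct symbol that breaks invariance.
#' Columns still variable within some group at `maxRank` are unranked (NA).
#' A k=2 group consensus and class-specific flag (invariant within each of
#' the two top-level groups, with differing non-gap consensuses) are
#' attached.
#'
#' @param msa A [ProteinMSA] whose names equal the tree's leaf labels.
#' @param tree A `phylo` tree.
#' @param maxRank Largest k examined (default: leaf count).
#' @return A [TraceResult].
#' @export
traceRanks <- function(msa, tree, maxRank = NULL) {
  stopifnot(is(msa, "ProteinMSA"))
  tree <- .rooted_for_trace(tree)
  if (!setequal(msa@names, tree$tip.label))
    .stopf("alignment names and tree leaves differ: %s",
           paste(c(setdiff(msa@names, tree$tip.label),
                   setdiff(tree$tip.label, msa@names)), collapse = ", "))
  n <- length(msa@names)
  if (is.null(maxRank)) maxRank <- n
  maxRank <- min(as.integer(maxRank), n)
  m <- as.matrix(msa)
  rank <- rep(NA_integer_, ncol(m))
  for (k in seq_len(maxRank)) {
    open <- is.na(rank)
    if (!any(open)) break
    part <- partitionTree(tree, k)
    inv <- .groups_invariant(m, part@groups)
    rank[open & inv] <- k
  }
  p2 <- if (n >= 2L) partitionTree(tree, 2L) else NULL
  consensus <- matrix(NA_character_, 2L, ncol(m))
  class_specific <- rep(FALSE, ncol(m))
  if (!is.null(p2)) {
    for (g in 1:2) {
      rows <- m[p2@groups[[g]], , drop = FALSE]
      same <- colSums(rows != rows[rep(1L, nrow(rows)), ,
                                   drop = FALSE]) == 0L
      consensus[g, same] <- rows[1L, same]
    }
    class_specific <- !is.na(consensus[1L, ]) & !is.na(consensus[2L, ]) &
      consensus[1L, ] != consensus[2L, ] &
      consensus[1L, ] != "-" & consensus[2L, ] != "-"
  }
  cols <- data.frame(column = seq_len(ncol(m)) - 1L, rank = rank,
                     class_specific = class_specific)
  new("TraceResult", columns = cols, consensus = consensus,
      maxRank = maxRank, msaRef = "msa", treeRef = "tree")
}

#' Class-specific trace columns under a two-group partition
#'
#' Columns invariant within each of the two groups with differing non-gap
#' consensus residues.
#'
#' @param trace A [TraceResult].
#' @param partition A [TracePartition] with exactly 2 groups (used for
#'   validation; the consensus stored in `trace` is k=2 based).
#' @return The subset of the trace column table that is class-specific, with
#'   the two group consensuses attached.
#' @export
classSpecificColumns <- function(trace, partition) {
  stopifnot(is(trace, "TraceResult"), is(partition, "TracePartition"))
  if (partition@k != 2L)
    .stopf("partition must have exactly 2 groups (got %d)", partition@k)
  sel <- trace@columns$class_specific
  out <- trace@columns[sel, , drop = FALSE]
  out$consensus_group1 <- trace@consensus[1L, sel]
  out$consensus_group2 <- trace@consensus[2L, sel]
  rownames(out) <- NULL
  out
}

#' Motif windows spelled by ranked group-consensus residues
#'
#' For each motif pattern and each group of `partition`, takes the columns
#' with trace rank at most `rankCutoff` where the group has a non-gap
#' invariant residue, spells them left to right with gaps skipped, and
#' reports every window of consecutive such columns matching the pattern
#' (X in a pattern matches any residue).
#'
#' @param trace A [TraceResult] from [traceRanks()].
#' @param msa The [ProteinMSA] the trace was computed on.
#' @param patterns A motif set from [defaultMotifSet()] (or compatible
#'   data.frame with `name` and `pattern`).
#' @param partition A [TracePartition] defining the row groups.
#' @param rankCutoff Largest rank considered conserved (default 3).
#' @return data.frame with pattern, group index, matched consensus text and
#'   the MSA columns (0-based, comma-joined) of each window.
#' @export
motifColumns <- function(trace, msa, patterns = defaultMotifSet(),
                         partition, rankCutoff = 3L) {
  stopifnot(is(trace, "TraceResult"), is(msa, "ProteinMSA"),
            is(partition, "TracePartition"))
  if (rankCutoff < 1L) .stopf("rankCutoff must be >= 1")
  m <- as.matrix(msa)
  out <- NULL
  for (g in seq_along(partition@groups)) {
    rows <- m[partition@groups[[g]], , drop = FALSE]
    same <- colSums(rows != rows[rep(1L, nrow(rows)), , drop = FALSE]) == 0L
    cons <- ifelse(same, rows[1L, ], NA_character_)
    eligible <- which(!is.na(trace@columns$rank) &
                        trace@columns$rank <= rankCutoff &
                        !is.na(cons) & cons != "-")
    if (!length(eligible)) next
    text <- paste(cons[eligible], collapse = "")
    for (p in seq_len(nrow(patterns))) {
      hits <- scanMotifs(text, patterns[p, , drop = FALSE])
      for (h in seq_len(nrow(hits))) {
        w <- eligible[hits$start[h]:(hits$start[h] +
                                       nchar(hits$matched_text[h]) - 1L)]
        out <- rbind(out, data.frame(
          pattern = patterns$name[p], group = g,
          matched_text = hits$matched_text[h],
          columns = paste(w - 1L, collapse = ","),
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out))
    out <- data.frame(pattern = character(), group = integer(),
                      matched_text = character(), columns = character(),
                      stringsAsFactors = FALSE)
  out
}
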