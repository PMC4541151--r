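#' Reference gene database
#'
#' Holds the curated nucleotide reference genes the homology search runs
#' against, with the GI number and species binomial parsed from FASTA headers
#' of the form \code{gi_<digits>_<Species_name>}, and an optional functional
#' group label per gene (\code{"ATPASE"}, \code{"MCO"} or \code{"UNKNOWN"}).
#'
#' @slot seqs A [Biostrings::DNAStringSet] named by record id.
#' @slot gi Character vector of GI numbers ("" when the header does not follow
#'   the convention).
#' @slot species Character vector of underscore-joined species names.
#' @slot group Character vector over \code{ATPASE}, \code{MCO}, \code{UNKNOWN}.
#' @slot name Database name.
#' @slot sourcePath Path the database was parsed from ("" if built in memory).
#'
#' @exportClass ReferenceDB
setClass("ReferenceDB",
  representation(
    seqs = "DNAStringSet",
    gi = "character",
    species = "character",
    group = "character",
    name = "character",
    sourcePath = "character"
  )
)

GENE_GROUPS <- c("ATPASE", "MCO", "UNKNOWN")

setValidity("ReferenceDB", function(object) {
  n <- length(object@seqs)
  if (n == 0L) return("empty database")
  ids <- names(object@seqs)
  if (is.null(ids) || anyDuplicated(ids))
    return("record ids must be present and unique")
  if (length(object@gi) != n || length(object@species) != n ||
      length(object@group) != n)
    return("gi, species and group must parallel the sequences")
  if (!all(object@group %in% GENE_GROUPS))
    return(sprintf("group labels must be one of %s",
                   paste(GENE_GROUPS, collapse = ", ")))
  w <- Biostrings::width(object@seqs)
  if (any(w < 60L))
    return(sprintf("reference sequences must be >= 60 nt (shortest: %d nt)",
                   min(w)))
  bad <- grepl("[^ACGTN]", as.character(object@seqs))
  if (any(bad))
    return(sprintf("non-IUPAC nucleotide characters in record '%s'",
                   ids[which(bad)[1L]]))
  TRUE
})

#' @describeIn ReferenceDB Number of reference genes.
#' @param x,object A `ReferenceDB`.
#' @export
setMethod("length", "ReferenceDB", function(x) length(x@seqs))

#' @describeIn ReferenceDB Record ids.
#' @export
setMethod("names", "ReferenceDB", function(x) names(x@seqs))

setMethod("show", "ReferenceDB", function(object) {
  cat(sprintf("ReferenceDB '%s': %d genes, %d--%d nt\n",
              object@name, length(object@seqs),
              min(Biostrings::width(object@seqs)),
              max(Biostrings::width(object@seqs))))
  tab <- table(factor(object@group, levels = GENE_GROUPS))
  cat(sprintf("  groups: ATPASE=%d MCO=%d UNKNOWN=%d\n",
              tab[["ATPASE"]], tab[["MCO"]], tab[["UNKNOWN"]]))
})

#' Sequences of a reference database
#' @param db A [ReferenceDB].
#' @return A [Biostrings::DNAStringSet].
#' @export
refSequences <- function(db) db@seqs

#' Group labels of a reference database
#' @param db A [ReferenceDB].
#' @return Named character vector of group labels.
#' @export
refGroups <- function(db) setNames(db@group, names(db@seqs))

#' Species labels of a reference database
#' @param db A [ReferenceDB].
#' @return Named character vector of species names parsed from headers.
#' @export
refSpecies <- function(db) setNames(db@species, names(db@seqs))

#' Search parameters for the seeded local nucleotide search
#'
#' Scoring and screening parameters of the BLASTN-like search stage. The
#' Karlin-Altschul pair (lambda, kappa) is solved/looked up by
#' [searchParams()]; lambda always satisfies the Karlin-Altschul identity for
#' (match, mismatch) under uniform base frequencies.
#'
#' @slot wordSize Integer seed word length (default 11).
#' @slot match,mismatch Integer match score (> 0) and mismatch score (< 0).
#' @slot gapOpen,gapExtend Non-negative gap penalties; a gap of length L costs
#'   gapOpen + L * gapExtend.
#' @slot lambda,kappa Karlin-Altschul parameters (lambda in nats).
#' @slot maxEvalue E-value screening cutoff (default 1e-4).
#' @slot minAlignLen Alignment-length screening cutoff in bp (default 40).
#' @slot minIdentityPct Identity screening cutoff in percent (default 0 = off).
#' @slot xDrop Ungapped extension X-drop (raw score units).
#'
#' @exportClass SearchParams
setClass("SearchParams",
  representation(
    wordSize = "integer", match = "integer", mismatch = "integer",
    gapOpen = "integer", gapExtend = "integer",
    lambda = "numeric", kappa = "numeric",
    maxEvalue = "numeric", minAlignLen = "integer",
    minIdentityPct = "numeric", xDrop = "numeric"
  )
)

setValidity("SearchParams", function(object) {
  if (object@wordSize < 4L) return("wordSize must be >= 4")
  if (!(object@match > 0L && object@mismatch < 0L))
    return("need match > 0 > mismatch")
  if (object@lambda <= 0 || object@kappa <= 0)
    return("lambda and kappa must be positive")
  p <- 0.25
  resid <- p * exp(object@lambda * object@match) +
    (1 - p) * exp(object@lambda * object@mismatch) - 1
  if (abs(resid) > 1e-9)
    return("lambda does not satisfy the Karlin-Altschul identity")
  TRUE
})

setMethod("show", "SearchParams", function(object) {
  cat(sprintf(
    "SearchParams: word=%d %+d/%+d gap %d/%d | lambda=%.4f K=%.3f | filters: len>=%d, E<=%g, id>=%g%%\n",
    object@wordSize, object@match, object@mismatch, object@gapOpen,
    object@gapExtend, object@lambda, object@kappa, object@minAlignLen,
    object@maxEvalue, object@minIdentityPct))
})

#' Protein multiple sequence alignment
#'
#' Equal-width gapped protein rows; ungapping any row reproduces the input
#' sequence exactly.
#'
#' @slot names Ordered sequence names.
#' @slot rows Gapped rows (characters over the amino-acid alphabet plus "-").
#'
#' @exportClass ProteinMSA
setClass("ProteinMSA",
  representation(names = "character", rows = "character"))

setValidity("ProteinMSA", function(object) {
  if (length(object@names) != length(object@rows))
    return("names and rows differ in length")
  if (length(object@rows) == 0L) return("empty alignment")
  if (length(unique(nchar(object@rows))) != 1L)
    return("rows differ in width")
  TRUE
})

#' @describeIn ProteinMSA Number of rows.
#' @param x,object A `ProteinMSA`.
#' @export
setMethod("length", "ProteinMSA", function(x) length(x@rows))

#' @describeIn ProteinMSA Sequence names.
#' @export
setMethod("names", "ProteinMSA", function(x) x@names)

#' @describeIn ProteinMSA Character matrix (rows x columns) of residues.
#' @export
setMethod("as.matrix", "ProteinMSA", function(x) {
  m <- do.call(rbind, strsplit(x@rows, "", fixed = TRUE))
  rownames(m) <- x@names
  m
})

setMethod("show", "ProteinMSA", function(object) {
  cat(sprintf("ProteinMSA: %d sequences x %d columns\n",
              length(object@rows), nchar(object@rows[1L])))
})

#' Rows of a protein alignment
#' @param msa A [ProteinMSA].
#' @return Named character vector of gapped rows.
#' @export
msaRows <- function(msa) setNames(msa@rows, msa@names)

#' Number of alignment columns
#' @param msa A [ProteinMSA].
#' @export
msaNcol <- function(msa) unname(nchar(msa@rows[1L]))

#' Build a ProteinMSA from gapped rows
#' @param rows Named character vector of equal-width gapped rows.
#' @return A [ProteinMSA].
#' @export
proteinMSA <- function(rows) {
  new("ProteinMSA", names = names(rows), rows = unname(rows))
}

#' Evolutionary-trace partition of tree leaves
#'
#' The k monophyletic groups obtained by cutting the k-1 earliest-diverging
#' internal nodes of a midpoint-rooted tree.
#'
#' @slot k Number of groups.
#' @slot groups List of character vectors of leaf names (disjoint, covering).
#'
#' @exportClass TracePartition
setClass("TracePartition",
  representation(k = "integer", groups = "list"))

setValidity("TracePartition", function(object) {
  if (length(object@groups) != object@k) return("|groups| must equal k")
  leaves <- unlist(object@groups)
  if (anyDuplicated(leaves)) return("groups must be disjoint")
  TRUE
})

setMethod("show", "TracePartition", function(object) {
  cat(sprintf("TracePartition: k=%d, group sizes %s\n", object@k,
              paste(lengths(object@groups), collapse = "/")))
})

#' Per-column evolutionary-trace ranks
#'
#' One row per alignment column; \code{rank} is the smallest number of
#' tree-defined groups within which the column is invariant (NA = unranked at
#' \code{maxRank}).
#'
#' @slot columns A data.frame with columns \code{column} (0-based),
#'   \code{rank} (integer or NA), \code{class_specific} (logical).
#' @slot consensus Character matrix (2 x columns) of k=2 group consensus
#'   residues (NA where a group is variable at that column).
#' @slot maxRank Largest k examined.
#' @slot msaRef,treeRef Names of the alignment/tree the trace was run on.
#'
#' @exportClass TraceResult
setClass("TraceResult",
  representation(columns = "data.frame", consensus = "matrix",
                 maxRank = "integer", msaRef = "character",
                 treeRef = "character"))

setMethod("show", "TraceResult", function(object) {
  ranked <- sum(!is.na(object@columns$rank))
  cat(sprintf(
    "TraceResult: %d columns (%d ranked at maxRank=%d, %d class-specific)\n",
    nrow(object@columns), ranked, object@maxRank,
    sum(object@columns$class_specific)))
})

#' Trace rank table
#' @param trace A [TraceResult].
#' @return The per-column data.frame.
#' @export
traceColumns <- function(trace) trace@columns
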