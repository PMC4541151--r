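# Metal-binding / ATP-binding motif screening of candidate CopA proteins and
# classification into the P-type ATPase vs multicopper-oxidase groups.

#' The default metal-binding and ATP-binding motif set
#'
#' Patterns over the amino-acid alphabet plus X (X matches any residue):
#' the P-type ATPase group uses Cys-based metal binding — CXXC (with HXXH as
#' a variant) at the N-terminal metal-binding domain, and the transmembrane
#' CPC (with YPC as an experimentally supported alternative) — plus the
#' GDGIN ATP-binding motif; the multicopper-oxidase group uses His-based HXH
#' metal binding. CXXC/HXXH are recorded but optional (about half of known
#' ATPase-group members lack the N-terminal CXXC).
#'
#' @return data.frame with columns `name`, `pattern`, `group`
#'   (ATPASE/MCO/BOTH), `category` (METAL_BINDING/ATP_BINDING), `required`.
#' @export
defaultMotifSet <- function() {
  data.frame(
    name = c("CXXC", "HXXH", "CPC", "YPC", "GDGIN", "HXH"),
    pattern = c("CXXC", "HXXH", "CPC", "YPC", "GDGIN", "HXH"),
    group = c("ATPASE", "ATPASE", "ATPASE", "ATPASE", "ATPASE", "MCO"),
    category = c("METAL_BINDING", "METAL_BINDING", "METAL_BINDING",
                 "METAL_BINDING", "ATP_BINDING", "METAL_BINDING"),
    required = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

# pattern -> regex: X matches any residue except X (query X satisfies no
# pattern position); literal residues match themselves only
.motif_regex <- function(pattern) {
  res <- paste(.aa_alphabet(), collapse = "")
  chartr_safe <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  paste(vapply(chartr_safe, function(ch)
    if (ch == "X") sprintf("[%s]", res) else ch, ""), collapse = "")
}

#' Scan a protein for motif occurrences
#'
#' Finds all (possibly overlapping) occurrences of each pattern, with
#' 1-based start positions on the ungapped protein, left to right. Pattern X
#' matches any of the 20 residues; a query X never satisfies any pattern
#' position.
#'
#' @param aa Protein sequence over the 20-letter alphabet plus X.
#' @param patterns Motif set data.frame (see [defaultMotifSet()]).
#' @return data.frame with `pattern_name`, `start`, `matched_text`.
#' @export
scanMotifs <- function(aa, patterns = defaultMotifSet()) {
  aa <- toupper(aa)
  out <- NULL
  for (p in seq_len(nrow(patterns))) {
    lookahead <- sprintf("(?=(%s))", .motif_regex(patterns$pattern[p]))
    m <- gregexpr(lookahead, aa, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    starts <- as.integer(m)
    width <- nchar(patterns$pattern[p])
    out <- rbind(out, data.frame(
      pattern_name = patterns$name[p], start = starts,
      matched_text = substring(aa, starts, starts + width - 1L),
      stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(pattern_name = character(), start = integer(),
                      matched_text = character(), stringsAsFactors = FALSE)
  out
}

#' Map candidate protein positions to reference-alignment columns
#'
#' The candidate is globally aligned to its nearest reference protein, which
#' must be a row of the reference alignment; candidate positions map through
#' the reference row's gap structure to MSA columns. Candidate positions
#' falling in candidate-only insertions (aligned to a reference gap) map to
#' NA.
#'
#' @param candidateAa Candidate protein sequence.
#' @param refName Name of the nearest reference row in `refMsa`.
#' @param refMsa A [ProteinMSA] containing the reference row.
#' @return Integer vector, one entry per candidate residue: the 1-based MSA
#'   column or NA.
#' @export
mapToReferenceAlignment <- function(candidateAa, refName, refMsa) {
  stopifnot(is(refMsa, "ProteinMSA"))
  if (!refName %in% refMsa@names)
    .stopf("reference '%s' is not a row of the alignment", refName)
  refRow <- msaRows(refMsa)[[refName]]
  refSeq <- gsub("-", "", refRow, fixed = TRUE)
  aln <- globalAlignPair(candidateAa, refSeq)
  ca <- strsplit(aln$alignment[1L], "", fixed = TRUE)[[1L]]
  ra <- strsplit(aln$alignment[2L], "", fixed = TRUE)[[1L]]
  # reference ungapped position -> MSA column
  rowChars <- strsplit(refRow, "", fixed = TRUE)[[1L]]
  refPosToCol <- which(rowChars != "-")
  map <- rep(NA_integer_, nchar(candidateAa))
  ci <- 0L; ri <- 0L
  for (k in seq_along(ca)) {
    if (ca[k] != "-") ci <- ci + 1L
    if (ra[k] != "-") ri <- ri + 1L
    if (ca[k] != "-" && ra[k] != "-") map[ci] <- refPosToCol[ri]
  }
  map
}

#' Classify a recovered gene into ATPASE / MCO / UNKNOWN
#'
#' Returns the group label of the nearest reference (the recovered gene's
#' `best_subject`, chosen upstream by highest identity with ties broken by
#' record id).
#'
#' @param gene One-row data.frame of a recovered gene (needs `best_subject`).
#' @param db The [ReferenceDB].
#' @return One of "ATPASE", "MCO", "UNKNOWN".
#' @export
classifyGroup <- function(gene, db) {
  sub <- gene$best_subject[1L]
  if (is.na(sub) || !sub %in% names(db@seqs)) return("UNKNOWN")
  unname(refGroups(db)[[sub]])
}

#' Functional screen of one candidate protein
#'
#' Default rules: an ATPASE-group candidate is HIGH_POTENTIAL iff it carries
#' at least one transmembrane metal-binding motif (CPC or the YPC
#' alternative) AND at least one GDGIN ATP-binding motif; CXXC/HXXH matches
#' are recorded but not required. An MCO-group candidate is HIGH_POTENTIAL
#' iff it carries at least `mcoMinHxh` (default 2) HXH occurrences at
#' distinct positions. UNKNOWN-group candidates are always
#' INSUFFICIENT_EVIDENCE. The rationale string enumerates each rule's
#' status; the call is a pure function of (matches, group).
#'
#' @param candidateAa Candidate protein (used only for reporting length).
#' @param groupCall "ATPASE", "MCO" or "UNKNOWN".
#' @param matches Motif matches from [scanMotifs()] on `candidateAa`.
#' @param mcoMinHxh Minimum number of distinct HXH sites for the MCO rule.
#' @return List with `functional_call` ("HIGH_POTENTIAL" or
#'   "INSUFFICIENT_EVIDENCE") and `rationale`.
#' @export
functionalScreen <- function(candidateAa, groupCall, matches,
                             mcoMinHxh = 2L) {
  count <- function(nm) sum(matches$pattern_name %in% nm)
  n_tm <- count(c("CPC", "YPC"))
  n_atp <- count("GDGIN")
  n_cxxc <- count(c("CXXC", "HXXH"))
  n_hxh <- length(unique(matches$start[matches$pattern_name == "HXH"]))
  if (groupCall == "ATPASE") {
    ok <- n_tm >= 1L && n_atp >= 1L
    rationale <- sprintf(
      "ATPASE rules: CPC/YPC %d (required, %s); GDGIN %d (required, %s); CXXC/HXXH %d (optional)",
      n_tm, if (n_tm >= 1L) "satisfied" else "missing",
      n_atp, if (n_atp >= 1L) "satisfied" else "missing", n_cxxc)
  } else if (groupCall == "MCO") {
    ok <- n_hxh >= mcoMinHxh
    rationale <- sprintf(
      "MCO rules: distinct HXH sites %d of >=%d required (%s)",
      n_hxh, mcoMinHxh, if (ok) "satisfied" else "missing")
  } else {
    ok <- FALSE
    rationale <- "group UNKNOWN: no rule set applies"
  }
  list(functional_call = if (ok) "HIGH_POTENTIAL" else
         "INSUFFICIENT_EVIDENCE",
       rationale = rationale)
}

#' Screen a set of curated recovered genes
#'
#' Runs [scanMotifs()] and [functionalScreen()] over every curated gene and
#' assembles the screening table.
#'
#' @param genes Curated genes from [curateCandidates()] (needs `aa`,
#'   `best_subject`, `group`).
#' @param db The [ReferenceDB].
#' @param patterns Motif set.
#' @param mcoMinHxh Passed to [functionalScreen()].
#' @return data.frame with per-gene group call, per-pattern counts,
#'   functional call and rationale.
#' @export
screenGenes <- function(genes, db, patterns = defaultMotifSet(),
                        mcoMinHxh = 2L) {
  if (nrow(genes) == 0L)
    return(data.frame(candidate_id = character(), group_call = character(),
                      functional_call = character(), rationale = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    gene <- genes[i, , drop = FALSE]
    grp <- if ("group" %in% colnames(gene) && !is.na(gene$group))
      gene$group else classifyGroup(gene, db)
    hits <- scanMotifs(gene$aa, patterns)
    call <- functionalScreen(gene$aa, grp, hits, mcoMinHxh)
    counts <- vapply(patterns$name, function(nm)
      sum(hits$pattern_name == nm), 0L)
    cbind(data.frame(candidate_id = sprintf("%s:%d-%d(%s)", gene$contig_id,
                                            gene$start, gene$end,
                                            gene$strand),
                     group_call = grp, stringsAsFactors = FALSE),
          as.data.frame(as.list(counts)),
          data.frame(functional_call = call$functional_call,
                     rationale = call$rationale, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
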