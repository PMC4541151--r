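# Full-length gene recovery: exhaustive six-frame ORF scanning on candidate
# contigs and assignment of screened homology hits to ORFs. Internal ORF
# coordinates are 0-based half-open on the contig forward strand; GFF3 output
# is 1-based inclusive.

STOP_CODONS <- c("TAA", "TAG", "TGA")

.empty_orfs <- function() {
  data.frame(contig_id = character(), start = integer(), end = integer(),
             strand = character(), frame = integer(), nt = character(),
             aa = character(), stringsAsFactors = FALSE)
}

# ORFs of one coding-strand sequence in one frame; returns codon-index
# intervals [start_idx, stop_idx] (1-based codon indices, stop inclusive)
.frame_orfs <- function(codons, start_codons, min_codons) {
  is_stop <- codons %in% STOP_CODONS
  is_start <- codons %in% start_codons
  stops <- which(is_stop)
  out <- NULL
  prev <- 0L
  for (st in stops) {
    if (st - prev >= min_codons) {
      cand <- which(is_start[(prev + 1L):(st - 1L)])
      if (length(cand)) {
        s_idx <- prev + cand[1L] # most upstream start sharing this stop
        if (st - s_idx + 1L >= min_codons)
          out <- rbind(out, c(s_idx, st))
      }
    }
    prev <- st
  }
  out
}

#' Find open reading frames on a contig (six frames, both strands)
#'
#' Reports every maximal start-to-in-frame-stop interval of at least
#' `minLenNt` nucleotides (start and stop codon included) in all six frames.
#' For nested starts sharing a stop the most upstream start is reported.
#' Translation uses the bacterial/archaeal code (table 11) with alternative
#' starts translated as Met; codons containing N translate to X.
#'
#' @param contig Nucleotide sequence (character or DNAString) over A,C,G,T,N.
#' @param id Contig id recorded in the output.
#' @param minLenNt Minimum ORF length in nucleotides, stop codon included
#'   (default 300).
#' @param startCodons Accepted start codons.
#' @return data.frame with columns `contig_id`, `start`, `end` (0-based
#'   half-open, forward strand), `strand`, `frame` (0-2 on the coding
#'   strand), `nt` (start through stop codon, coding orientation), `aa`
#'   (no terminal stop, leading residue M). Empty when no ORF qualifies.
#' @export
findOrfs <- function(contig, id = "contig", minLenNt = 300L,
                     startCodons = c("ATG", "GTG", "TTG")) {
  contig <- toupper(as.character(contig))
  L <- nchar(contig)
  min_codons <- max(2L, as.integer(ceiling(minLenNt / 3)))
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else .revcomp(contig)
    for (f in 0:2) {
      ncod <- (L - f) %/% 3L
      if (ncod < min_codons) next
      pos <- f + 1L + 3L * (seq_len(ncod) - 1L)
      codons <- substring(s, pos, pos + 2L)
      iv <- .frame_orfs(codons, startCodons, min_codons)
      if (is.null(iv)) next
      for (r in seq_len(nrow(iv))) {
        cs <- f + (iv[r, 1L] - 1L) * 3L          # 0-based on coding strand
        ce <- f + iv[r, 2L] * 3L
        nt <- substr(s, cs + 1L, ce)
        aa <- .translate_nt(substr(nt, 1L, nchar(nt) - 3L))
        substr(aa, 1L, 1L) <- "M"
        if (strand == "+") {
          st <- cs; en <- ce
        } else {
          st <- L - ce; en <- L - cs
        }
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = id, start = st, end = en, strand = strand,
          frame = f, nt = nt, aa = aa, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(.empty_orfs())
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

#' Assign screened homology hits to ORFs and build recovered genes
#'
#' Each hit is assigned to the ORF on the matching strand with maximal
#' overlap, provided the overlap covers at least `minOverlapFrac` of the
#' hit's contig interval. Hits assigned to the same ORF merge into one
#' recovered gene whose `best_subject` is the highest-identity hit's subject
#' (ties broken by subject id). Unassigned hits are returned separately as
#' fragment-only evidence.
#'
#' @param hits Screened hits for one or more contigs (see [filterHits()]).
#' @param orfs ORFs from [findOrfs()] for the same contigs.
#' @param minOverlapFrac Minimum fraction of the hit interval covered by the
#'   ORF (default 0.5).
#' @return List with `genes` (data.frame of recovered genes: ORF fields plus
#'   `best_subject`, `best_identity_pct`, `overlap_frac`, `n_hits`) and
#'   `fragment_only` (hits data.frame).
#' @export
mapHitsToOrfs <- function(hits, orfs, minOverlapFrac = 0.5) {
  genes <- cbind(.empty_orfs(),
                 data.frame(best_subject = character(),
                            best_identity_pct = numeric(),
                            overlap_frac = numeric(), n_hits = integer(),
                            stringsAsFactors = FALSE))
  if (nrow(hits) == 0L)
    return(list(genes = genes, fragment_only = hits))
  assignment <- integer(nrow(hits))  # 0 = unassigned
  ovfrac <- numeric(nrow(hits))
  for (h in seq_len(nrow(hits))) {
    h0 <- hits$q_start[h] - 1L # 0-based half-open hit interval
    h1 <- hits$q_end[h]
    cand <- which(orfs$contig_id == hits$query_id[h] &
                    orfs$strand == hits$strand[h])
    if (!length(cand)) next
    ov <- pmax(0L, pmin(orfs$end[cand], h1) - pmax(orfs$start[cand], h0))
    frac <- ov / (h1 - h0)
    best <- which.max(ov)
    if (frac[best] >= minOverlapFrac) {
      assignment[h] <- cand[best]
      ovfrac[h] <- frac[best]
    }
  }
  rows <- list()
  for (oi in sort(unique(assignment[assignment > 0L]))) {
    hs <- which(assignment == oi)
    sub <- hits[hs, , drop = FALSE]
    best <- order(-sub$identity_pct, sub$subject_id)[1L]
    rows[[length(rows) + 1L]] <- cbind(
      orfs[oi, , drop = FALSE],
      data.frame(best_subject = sub$subject_id[best],
                 best_identity_pct = sub$identity_pct[best],
                 overlap_frac = ovfrac[hs][best],
                 n_hits = length(hs), stringsAsFactors = FALSE))
  }
  if (length(rows)) {
    genes <- do.call(rbind, rows)
    rownames(genes) <- NULL
  }
  list(genes = genes,
       fragment_only = hits[assignment == 0L, , drop = FALSE])
}

#' Curate recovered genes by nearest-reference identity
#'
#' Keeps recovered genes whose best-reference identity is at least
#' `minIdentityPct` (default 70) and annotates each survivor with the group
#' label of its nearest reference.
#'
#' @param genes Recovered genes from [mapHitsToOrfs()].
#' @param db The [ReferenceDB].
#' @param minIdentityPct Identity cutoff in percent.
#' @return Curated data.frame with an added `group` column.
#' @export
curateCandidates <- function(genes, db, minIdentityPct = 70) {
  if (nrow(genes) == 0L) {
    genes$group <- character(0)
    return(genes)
  }
  out <- genes[genes$best_identity_pct >= minIdentityPct, , drop = FALSE]
  out$group <- unname(refGroups(db)[out$best_subject])
  rownames(out) <- NULL
  out
}

#' Convert ORFs or recovered genes to GRanges / GFF3
#'
#' @param orfs data.frame from [findOrfs()] or [mapHitsToOrfs()].
#' @return A [GenomicRanges::GRanges] (1-based inclusive coordinates) with
#'   sequence and annotation columns in `mcols`.
#' @export
orfsToGRanges <- function(orfs) {
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(orfs)) orfs$contig_id else character(),
    ranges = IRanges::IRanges(start = orfs$start + 1L, end = orfs$end),
    strand = if (nrow(orfs)) orfs$strand else character())
  keep <- setdiff(colnames(orfs), c("contig_id", "start", "end", "strand"))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(orfs[, keep, drop = FALSE])
  gr
}

#' @rdname orfsToGRanges
#' @param gr A GRanges as produced by [orfsToGRanges()] or read back from
#'   GFF3.
#' @return For `grangesToOrfs`: the 0-based half-open data.frame form.
#' @export
grangesToOrfs <- function(gr) {
  df <- data.frame(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  mc <- as.data.frame(S4Vectors::mcols(gr))
  for (col in c("frame", "nt", "aa", "best_subject", "best_identity_pct",
                "overlap_frac", "n_hits", "group")) {
    if (col %in% colnames(mc)) df[[col]] <- mc[[col]]
  }
  if ("frame" %in% colnames(df)) df$frame <- as.integer(df$frame)
  df
}

#' Write recovered genes as GFF3
#'
#' Feature type "gene"; `best_subject`, identity and overlap fraction are
#' carried as attributes when present.
#'
#' @param orfs data.frame of ORFs or recovered genes.
#' @param path Output path.
#' @param featureType GFF3 feature type.
#' @return `path`, invisibly.
#' @export
writeGenesGFF3 <- function(orfs, path, featureType = "gene") {
  if (nrow(orfs) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- orfsToGRanges(orfs[, setdiff(colnames(orfs), c("nt", "aa")),
                           drop = FALSE])
  S4Vectors::mcols(gr)$type <- featureType
  S4Vectors::mcols(gr)$ID <- sprintf("%s_g%d",
                                     as.character(GenomicRanges::seqnames(gr)),
                                     seq_along(gr))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read genes back from GFF3 into the 0-based data.frame form
#'
#' @param path GFF3 path.
#' @return data.frame with `contig_id`, `start`, `end`, `strand` plus any
#'   annotation attributes present.
#' @export
readGenesGFF3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  grangesToOrfs(gr)
}
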