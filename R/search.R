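# Seeded local nucleotide search of contigs against the reference database:
# exact word seeding, two-way ungapped X-drop extension, then affine-gap
# local alignment in a window around the chained seed segments.

HIT_COLUMNS <- c("query_id", "subject_id", "identity_pct", "align_len",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bit_score",
                 "raw_score", "strand", "matches")

.empty_hits <- function() {
  df <- data.frame(query_id = character(), subject_id = character(),
                   identity_pct = numeric(), align_len = integer(),
                   mismatches = integer(), gap_opens = integer(),
                   q_start = integer(), q_end = integer(),
                   s_start = integer(), s_end = integer(),
                   evalue = numeric(), bit_score = numeric(),
                   raw_score = numeric(), strand = character(),
                   matches = integer(), stringsAsFactors = FALSE)
  df
}

# rolling integer codes for all words of length w; NA where the window
# contains N (or runs off the end)
.word_codes <- function(v, w) {
  L <- length(v)
  npos <- L - w + 1L
  if (npos < 1L) return(integer(0))
  code <- integer(npos)
  vv <- v
  vv[vv == 4L] <- 0L # placeholder; N windows masked below
  for (k in seq_len(w)) code <- code * 4L + vv[k:(k + npos - 1L)]
  cn <- cumsum(v == 4L)
  n_in <- cn[w:L] - c(0L, cn)[1:npos]
  code[n_in > 0L] <- NA_integer_
  code
}

#' Build an exact-word seed index over a reference database
#'
#' Maps every word of length `wordSize` (excluding words containing N) to its
#' (subject, offset) occurrences. Total indexed positions equal
#' \eqn{\sum (len_i - wordSize + 1)} minus N-containing windows.
#'
#' @param db A [ReferenceDB].
#' @param wordSize Word length.
#' @return An object of class `SeedIndex` with fields `wordSize`, `codes`
#'   (sorted unique word codes), `hits` (list parallel to `codes`; each a
#'   2-column matrix of subject index and 1-based offset), `subjects`,
#'   `nIndexed` and `dbLength`.
#' @export
buildWordIndex <- function(db, wordSize = 11L) {
  stopifnot(is(db, "ReferenceDB"))
  wordSize <- as.integer(wordSize)
  w <- Biostrings::width(db@seqs)
  if (any(w < wordSize)) {
    short <- names(db@seqs)[which.min(w)]
    .stopf("wordSize %d exceeds length of reference '%s' (%d nt)",
           wordSize, short, min(w))
  }
  chr <- as.character(db@seqs)
  all_codes <- vector("list", length(chr))
  all_subj <- vector("list", length(chr))
  all_off <- vector("list", length(chr))
  for (i in seq_along(chr)) {
    codes <- .word_codes(.encode_dna(chr[[i]]), wordSize)
    keep <- !is.na(codes)
    all_codes[[i]] <- codes[keep]
    all_off[[i]] <- which(keep)
    all_subj[[i]] <- rep.int(i, sum(keep))
  }
  codes <- unlist(all_codes)
  subj <- unlist(all_subj)
  off <- unlist(all_off)
  o <- order(codes)
  codes <- codes[o]; subj <- subj[o]; off <- off[o]
  ucodes <- unique(codes)
  grp <- cumsum(!duplicated(codes))
  hits <- split.data.frame(cbind(subject = subj, offset = off), grp)
  names(hits) <- NULL
  structure(list(wordSize = wordSize, codes = ucodes, hits = hits,
                 subjects = names(db@seqs), nIndexed = length(codes),
                 dbLength = sum(w)),
            class = "SeedIndex")
}

#' @export
print.SeedIndex <- function(x, ...) {
  cat(sprintf("SeedIndex: word=%d, %d positions over %d subjects (%d nt)\n",
              x$wordSize, x$nIndexed, length(x$subjects), x$dbLength))
  invisible(x)
}

# two-way ungapped X-drop extension of an exact seed; returns 1-based
# inclusive segment coordinates on (qi, si) and the ungapped score
.xdrop_extend <- function(qi, si, qpos, spos, w, match, mismatch, xdrop) {
  score_run <- function(qv, sv) {
    if (!length(qv)) return(c(0L, 0))
    sc <- ifelse(qv == sv & qv < 4L, match, mismatch)
    cm <- cumsum(sc)
    pm <- cummax(cm)
    stop_at <- which(pm - cm > xdrop)
    lim <- if (length(stop_at)) stop_at[1L] - 1L else length(cm)
    if (lim < 1L) return(c(0L, 0))
    best <- which.max(cm[seq_len(lim)])
    if (cm[best] <= 0) c(0L, 0) else c(best, cm[best])
  }
  nR <- min(length(qi) - (qpos + w - 1L), length(si) - (spos + w - 1L))
  right <- if (nR > 0L)
    score_run(qi[(qpos + w):(qpos + w - 1L + nR)],
              si[(spos + w):(spos + w - 1L + nR)]) else c(0L, 0)
  nL <- min(qpos - 1L, spos - 1L)
  left <- if (nL > 0L)
    score_run(rev(qi[(qpos - nL):(qpos - 1L)]),
              rev(si[(spos - nL):(spos - 1L)])) else c(0L, 0)
  out <- c(qpos - left[1L], qpos + w - 1L + right[1L],
           spos - left[1L], spos + w - 1L + right[1L],
           w * match + left[2L] + right[2L])
  names(out) <- c("qs", "qe", "ss", "se", "score")
  out
}

# gapped alignment of one chained seed cluster inside an expanding window
.windowed_sw <- function(qi, si, qlo, qhi, slo, shi, params) {
  pad_grow <- 4
  repeat {
    res <- .C_sw_affine(qi[qlo:qhi], si[slo:shi],
                        params@match, params@mismatch,
                        params@gapOpen, params@gapExtend)
    touches <- (res$q_start == 1L && qlo > 1L) ||
      (res$q_end == qhi - qlo + 1L && qhi < length(qi)) ||
      (res$s_start == 1L && slo > 1L) ||
      (res$s_end == shi - slo + 1L && shi < length(si))
    if (!touches) break
    span <- max(qhi - qlo, shi - slo) + 1L
    qlo <- max(1L, qlo - span * pad_grow)
    qhi <- min(length(qi), qhi + span * pad_grow)
    slo <- max(1L, slo - span * pad_grow)
    shi <- min(length(si), shi + span * pad_grow)
  }
  res$q_start <- res$q_start + qlo - 1L
  res$q_end <- res$q_end + qlo - 1L
  res$s_start <- res$s_start + slo - 1L
  res$s_end <- res$s_end + slo - 1L
  res
}

# search one strand-oriented query against all seeded subjects
.search_strand <- function(qi, index, ref_int, params) {
  w <- index$wordSize
  codes <- .word_codes(qi, w)
  idx <- match(codes, index$codes)
  qpos <- which(!is.na(idx))
  if (!length(qpos)) return(list())
  seeds <- do.call(rbind, lapply(qpos, function(p) {
    m <- index$hits[[idx[p]]]
    cbind(qpos = rep.int(p, nrow(m)), m)
  }))
  out <- list()
  for (sj in unique(seeds[, "subject"])) {
    ss <- seeds[seeds[, "subject"] == sj, , drop = FALSE]
    diag <- ss[, "qpos"] - ss[, "offset"]
    o <- order(diag, ss[, "qpos"])
    ss <- ss[o, , drop = FALSE]; diag <- diag[o]
    si <- ref_int[[sj]]
    segs <- list()
    cov_end <- new.env(parent = emptyenv())
    for (r in seq_len(nrow(ss))) {
      d <- as.character(diag[r])
      qp <- ss[r, "qpos"]
      prev <- get0(d, envir = cov_end, ifnotfound = -1L)
      if (qp + w - 1L <= prev) next
      seg <- .xdrop_extend(qi, si, qp, ss[r, "offset"], w,
                           params@match, params@mismatch, params@xDrop)
      assign(d, seg[["qe"]], envir = cov_end)
      segs[[length(segs) + 1L]] <- seg
    }
    segm <- do.call(rbind, segs)
    segm <- segm[order(segm[, "qs"]), , drop = FALSE]
    # chain segments into loci: a new locus opens after a >200 bp query gap
    cluster <- cumsum(c(TRUE, segm[-1L, "qs"] >
                          cummax(segm[, "qe"])[-nrow(segm)] + 200L))
    for (cl in unique(cluster)) {
      cs <- segm[cluster == cl, , drop = FALSE]
      pad <- 100L
      aln <- .windowed_sw(qi, si,
                          max(1L, min(cs[, "qs"]) - pad),
                          min(length(qi), max(cs[, "qe"]) + pad),
                          max(1L, min(cs[, "ss"]) - pad),
                          min(length(si), max(cs[, "se"]) + pad),
                          params)
      aln$subject <- sj
      out[[length(out) + 1L]] <- aln
    }
  }
  out
}

#' Search one contig against the reference database
#'
#' Scans the contig forward and reverse-complement, seeds exact word matches
#' through the index, extends seeds ungapped with an X-drop, then computes an
#' affine-gap local alignment around each chained seed locus. Coordinates of
#' every hit are reported on the contig's forward strand with a strand flag;
#' hits above the E-value cutoff are still returned (screening is a separate
#' stage, see [filterHits()]). Overlapping alignments to the same subject and
#' strand are merged keeping the highest raw score.
#'
#' @param contig Nucleotide sequence (character or DNAString).
#' @param id Contig id.
#' @param index A `SeedIndex` from [buildWordIndex()].
#' @param db The [ReferenceDB] the index was built from.
#' @param params A [SearchParams].
#' @return data.frame of hits (zero rows when the contig is shorter than the
#'   word size, with a warning).
#' @export
searchContig <- function(contig, id, index, db, params = searchParams()) {
  contig <- toupper(as.character(contig))
  if (nchar(contig) < index$wordSize) {
    .warnf("contig '%s' shorter than word size %d; skipped", id,
           index$wordSize)
    return(.empty_hits())
  }
  ref_int <- lapply(as.character(db@seqs), .encode_dna)
  L <- nchar(contig)
  rows <- list()
  for (strand in c("+", "-")) {
    qseq <- if (strand == "+") contig else .revcomp(contig)
    qi <- .encode_dna(qseq)
    alns <- .search_strand(qi, index, ref_int, params)
    for (a in alns) {
      if (strand == "+") {
        qs <- a$q_start; qe <- a$q_end
      } else {
        qs <- L - a$q_end + 1L; qe <- L - a$q_start + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = id, subject_id = index$subjects[a$subject],
        identity_pct = 100 * a$matches / a$align_len,
        align_len = a$align_len, mismatches = a$mismatches,
        gap_opens = a$gap_opens, q_start = qs, q_end = qe,
        s_start = a$s_start, s_end = a$s_end,
        evalue = NA_real_, bit_score = NA_real_,
        raw_score = a$score, strand = strand, matches = a$matches,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_hits())
  hits <- do.call(rbind, rows)
  hits <- .merge_overlapping_hits(hits)
  ev <- scoreToEvalue(hits$raw_score, m = L, n = index$dbLength, params)
  hits$bit_score <- ev$bit_score
  hits$evalue <- ev$evalue
  hits[order(-hits$raw_score, hits$subject_id), ]
}

# keep the highest-scoring of any pair of same-subject same-strand hits that
# overlap on both query and subject
.merge_overlapping_hits <- function(hits) {
  keep <- rep(TRUE, nrow(hits))
  o <- order(-hits$raw_score)
  for (a in seq_along(o)) {
    i <- o[a]
    if (!keep[i]) next
    for (b in seq_len(a - 1L)) {
      j <- o[b]
      if (!keep[j]) next
      if (hits$subject_id[i] == hits$subject_id[j] &&
          hits$strand[i] == hits$strand[j] &&
          hits$q_start[i] <= hits$q_end[j] &&
          hits$q_end[i] >= hits$q_start[j] &&
          hits$s_start[i] <= hits$s_end[j] &&
          hits$s_end[i] >= hits$s_start[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  hits[keep, , drop = FALSE]
}

#' Search many contigs against the reference database
#'
#' @param contigs Named [Biostrings::DNAStringSet] (or named character
#'   vector) of assembled contigs.
#' @param db A [ReferenceDB].
#' @param params A [SearchParams].
#' @param index Optional prebuilt `SeedIndex` (rebuilt from `params@wordSize`
#'   otherwise).
#' @return data.frame of hits across all contigs.
#' @export
searchContigs <- function(contigs, db, params = searchParams(),
                          index = NULL) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  if (is.null(index)) index <- buildWordIndex(db, params@wordSize)
  if (length(contigs) == 0L) return(.empty_hits())
  ids <- names(contigs)
  if (is.null(ids)) .stopf("contigs must be named")
  res <- lapply(seq_along(contigs), function(i)
    searchContig(as.character(contigs[[i]]), ids[i], index, db, params))
  do.call(rbind, res)
}

#' Screen hits on alignment length, E-value and identity
#'
#' Keeps hits with `align_len >= minAlignLen` (threshold-inclusive), `evalue
#' <= maxEvalue` and `identity_pct >= minIdentityPct`; output is sorted by
#' alignment length descending, ties by E-value ascending, then subject id.
#'
#' @param hits data.frame from [searchContigs()].
#' @param params A [SearchParams] carrying the cutoffs.
#' @return The screened, sorted data.frame.
#' @export
filterHits <- function(hits, params = searchParams()) {
  if (nrow(hits) == 0L) return(hits)
  keep <- hits$align_len >= params@minAlignLen &
    hits$evalue <= params@maxEvalue &
    hits$identity_pct >= params@minIdentityPct
  out <- hits[keep, , drop = FALSE]
  out[order(-out$align_len, out$evalue, out$subject_id), , drop = FALSE]
}

#' Contigs carrying at least one surviving hit
#'
#' @param hits Screened hits from [filterHits()].
#' @return Character vector of unique contig ids.
#' @export
candidateContigs <- function(hits) unique(hits$query_id)

#' Write hits as 12-column BLAST-style tabular output
#'
#' Standard outfmt-6 column order: qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore. Minus-strand hits
#' follow the BLAST convention of swapped subject coordinates.
#'
#' @param hits Hits data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeHitsTSV <- function(hits, path) {
  out <- hits[, HIT_COLUMNS[1:12]]
  minus <- hits$strand == "-"
  tmp <- out$s_start[minus]
  out$s_start[minus] <- out$s_end[minus]
  out$s_end[minus] <- tmp
  out$identity_pct <- sprintf("%.2f", out$identity_pct)
  out$evalue <- sprintf("%.2e", out$evalue)
  out$bit_score <- sprintf("%.1f", out$bit_score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read BLAST-style tabular hits written by [writeHitsTSV()]
#'
#' @param path TSV path.
#' @return Hits data.frame (strand restored from subject coordinate order;
#'   `raw_score` and `matches` are reconstructed approximately from the bit
#'   score and identity).
#' @export
readHitsTSV <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = HIT_COLUMNS[1:12],
                    colClasses = c("character", "character", rep("numeric", 10)))
  strand <- ifelse(tab$s_start <= tab$s_end, "+", "-")
  minus <- strand == "-"
  tmp <- tab$s_start[minus]
  tab$s_start[minus] <- tab$s_end[minus]
  tab$s_end[minus] <- tmp
  tab$strand <- strand
  tab$raw_score <- NA_real_
  tab$matches <- as.integer(round(tab$identity_pct * tab$align_len / 100))
  for (col in c("align_len", "mismatches", "gap_opens", "q_start", "q_end",
                "s_start", "s_end"))
    tab[[col]] <- as.integer(tab[[col]])
  tab
}
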