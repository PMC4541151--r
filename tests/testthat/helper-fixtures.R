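# Fixtures and independent brute-force oracles shared across the suite.
# All fixtures are generated in code; nothing is read from disk.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

rand_protein <- function(n) paste(sample(AA20, n, TRUE), collapse = "")

# small reference database of random genes with convention headers
make_random_db <- function(n = 5L, len = 500L, seed = 42L) {
  withr::with_seed(seed, {
    seqs <- setNames(vapply(seq_len(n), function(i) rand_dna(len), ""),
                     sprintf("gi_%09d_Test_sp%02d", 100000000L + seq_len(n),
                             seq_len(n)))
    referenceDB(seqs)
  })
}

write_temp_fasta <- function(seqs, width = 60L) {
  path <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = width)
  path
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# a synthetic hit row for filter/sort tests
.make_hit_row <- function(align_len = 100L, evalue = 1e-10,
                          subject = "s1", query = "c1", identity = 95) {
  data.frame(query_id = query, subject_id = subject,
             identity_pct = identity, align_len = align_len,
             mismatches = 2L, gap_opens = 0L, q_start = 1L,
             q_end = align_len, s_start = 1L, s_end = align_len,
             evalue = evalue, bit_score = 50, raw_score = 40,
             strand = "+", matches = align_len - 2L,
             stringsAsFactors = FALSE)
}

# ---- independent ORF oracle: plain per-frame while-loop scanner -----------

GENETIC_CODE11 <- Biostrings::getGeneticCode("11")

oracle_translate <- function(codons) {
  aa <- unname(GENETIC_CODE11[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

oracle_orfs <- function(contig, min_len_nt = 300L,
                        starts = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(contig)
  out <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else revcomp(contig)
    for (f in 0:2) {
      i <- f + 1L
      current_start <- NA_integer_
      while (i + 2L <= L) {
        codon <- substr(s, i, i + 2L)
        if (is.na(current_start) && codon %in% starts) current_start <- i
        if (codon %in% stops) {
          if (!is.na(current_start)) {
            len <- i + 3L - current_start
            if (len >= min_len_nt) {
              cs <- current_start - 1L
              ce <- i + 2L
              if (strand == "+") {
                st <- cs; en <- ce
              } else {
                st <- L - ce; en <- L - cs
              }
              out <- rbind(out, data.frame(start = st, end = en,
                                           strand = strand,
                                           stringsAsFactors = FALSE))
            }
          }
          current_start <- NA_integer_
        }
        i <- i + 3L
      }
    }
  }
  if (is.null(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

# ---- naive motif-scan oracle: explicit sliding window ---------------------

oracle_scan <- function(aa, pattern) {
  pv <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  av <- strsplit(aa, "", fixed = TRUE)[[1L]]
  w <- length(pv)
  hits <- integer(0)
  if (length(av) >= w) {
    for (i in seq_len(length(av) - w + 1L)) {
      win <- av[i:(i + w - 1L)]
      ok <- TRUE
      for (k in seq_len(w)) {
        if (pv[k] == "X") {
          if (!(win[k] %in% AA20)) { ok <- FALSE; break }
        } else if (win[k] != pv[k]) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, i)
    }
  }
  hits
}

# ---- exhaustive evolutionary-trace rank oracle ----------------------------

oracle_trace_ranks <- function(msa, tree, max_rank) {
  m <- as.matrix(msa)
  ranks <- rep(NA_integer_, ncol(m))
  for (col in seq_len(ncol(m))) {
    for (k in seq_len(max_rank)) {
      groups <- partitionGroups(partitionTree(tree, k))
      all_inv <- TRUE
      for (g in groups) {
        vals <- m[g, col]
        if (length(unique(vals)) > 1L) { all_inv <- FALSE; break }
      }
      if (all_inv) { ranks[col] <- k; break }
    }
  }
  ranks
}

# ---- linear-gap global alignment oracle (plain DP, no affine states) ------

oracle_nw_linear <- function(a, b, gap) {
  B <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1L] <- -(0:n) * gap
  D[1L, ] <- -(0:m) * gap
  for (i in seq_len(n))
    for (j in seq_len(m))
      D[i + 1L, j + 1L] <- max(D[i, j] + B[av[i], bv[j]],
                               D[i, j + 1L] - gap,
                               D[i + 1L, j] - gap)
  D[n + 1L, m + 1L]
}
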