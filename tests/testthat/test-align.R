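test_that("self-alignment scores the BLOSUM62 diagonal with no gaps", {
  s <- "PAWHEAE"
  aln <- globalAlignPair(s, s)
  B <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  letters_s <- strsplit(s, "", fixed = TRUE)[[1]]
  expect_equal(aln$score, sum(B[cbind(letters_s, letters_s)]))
  expect_equal(aln$alignment, c(s, s))
})

test_that("empty or invalid sequences are rejected with position info", {
  expect_error(globalAlignPair("A", ""), "empty")
  expect_error(globalAlignPair("ACDB5F", "ACD"), "position 4")
})

test_that("affine scores match the Biostrings global aligner on random pairs", {
  B <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  withr::with_seed(21, {
    for (rep in 1:15) {
      a <- rand_protein(sample(10:80, 1))
      b <- rand_protein(sample(10:80, 1))
      mine <- globalAlignPair(a, b)
      orc <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                           substitutionMatrix = B,
                                           gapOpening = 10,
                                           gapExtension = 1)
      expect_equal(mine$score, Biostrings::score(orc))
      # and the aligned rows ungap back to the inputs
      expect_equal(gsub("-", "", mine$alignment[1], fixed = TRUE), a)
      expect_equal(gsub("-", "", mine$alignment[2], fixed = TRUE), b)
    }
  })
})

test_that("with zero opening cost the affine aligner reduces to plain linear-gap DP", {
  withr::with_seed(22, {
    for (rep in 1:10) {
      a <- rand_protein(sample(10:60, 1))
      b <- rand_protein(sample(10:60, 1))
      mine <- globalAlignPair(a, b, gapOpen = 0, gapExtend = 4)
      expect_equal(mine$score, oracle_nw_linear(a, b, gap = 4))
    }
  })
})

test_that("percent identity counts co-ungapped columns only", {
  expect_equal(percentIdentity(c("ACDE", "ACDE")), 100)
  expect_equal(percentIdentity(c("AB-C", "AB-D")), 100 * 2 / 3,
               tolerance = 1e-9)
  expect_warning(pid <- percentIdentity(c("AC--", "--AC")), "no co-ungapped")
  expect_equal(pid, 0)
  expect_error(percentIdentity(c("AC", "ACD")), "differ in length")
})

test_that("progressive alignment of identical sequences introduces no gaps", {
  seqs <- setNames(rep("MKVLITAHACDE", 4), paste0("s", 1:4))
  msa <- progressiveMsa(seqs)
  expect_false(any(grepl("-", msaRows(msa), fixed = TRUE)))
  expect_equal(msaNcol(msa), 12L)
})

test_that("two sequences reduce exactly to the pairwise aligner", {
  withr::with_seed(23, {
    a <- rand_protein(40); b <- rand_protein(35)
  })
  msa <- progressiveMsa(c(x = a, y = b))
  aln <- globalAlignPair(a, b)
  expect_equal(unname(msaRows(msa)), aln$alignment)
  expect_error(progressiveMsa(c(only = a)), "nothing to align")
})

test_that("ungapping any MSA row reproduces its input; width bounds hold", {
  withr::with_seed(24, {
    seqs <- setNames(vapply(1:6, function(i)
      rand_protein(sample(30:60, 1)), ""), paste0("s", 1:6))
  })
  msa <- progressiveMsa(seqs)
  rows <- msaRows(msa)
  expect_equal(names(rows), names(seqs)) # input row order preserved
  for (nm in names(seqs))
    expect_equal(gsub("-", "", rows[[nm]], fixed = TRUE), seqs[[nm]])
  expect_gte(msaNcol(msa), max(nchar(seqs)))
})

test_that("related sequences align with motif columns shared", {
  withr::with_seed(25, {
    anc <- rand_protein(60)
    substr(anc, 25, 27) <- "CPC"
    seqs <- vapply(1:5, function(i) {
      v <- strsplit(anc, "", fixed = TRUE)[[1]]
      at <- sample(setdiff(1:60, 25:27), 8)
      v[at] <- vapply(at, function(k) sample(setdiff(AA20, v[k]), 1), "")
      paste(v, collapse = "")
    }, "")
    names(seqs) <- paste0("s", 1:5)
  })
  msa <- progressiveMsa(seqs)
  m <- as.matrix(msa)
  cpc_cols <- which(apply(m, 2, function(col) all(col == col[1]) &&
                            col[1] == "C"))
  expect_gte(length(cpc_cols), 2L)
})

test_that("block trimming keeps fully conserved alignments whole and drops junk", {
  msa <- proteinMSA(setNames(rep(paste(rep("ACDEF", 10), collapse = ""), 4),
                             paste0("s", 1:4)))
  tr <- trimConservedBlocks(msa)
  expect_equal(tr$blocks, data.frame(start = 0L, end = 50L))
  expect_equal(msaNcol(tr$msa), 50L)
  # all-distinct columns: no block survives
  junk <- proteinMSA(c(a = "ACDEFGHIKLMN", b = "CDEFGHIKLMNP",
                       c = "DEFGHIKLMNPQ"))
  expect_warning(tr2 <- trimConservedBlocks(junk), "no conserved block")
  expect_equal(nrow(tr2$blocks), 0L)
})

test_that("a long non-conserved run splits the alignment into two blocks", {
  withr::with_seed(26, {
    cons1 <- rand_protein(12)
    cons2 <- rand_protein(12)
    # junk columns are all-distinct across rows by construction
    rows <- vapply(1:4, function(i)
      paste0(cons1, paste(rep(AA20[i], 9), collapse = ""), cons2), "")
    names(rows) <- paste0("s", 1:4)
  })
  tr <- trimConservedBlocks(proteinMSA(rows), minBlockLen = 10L,
                            maxNonconsRun = 8L)
  expect_equal(nrow(tr$blocks), 2L)
  expect_equal(tr$blocks$start, c(0L, 21L))
  expect_equal(tr$blocks$end, c(12L, 33L))
  expect_equal(msaNcol(tr$msa), 24L)
})

test_that("raising the conservation fraction never increases kept columns", {
  withr::with_seed(27, {
    anc <- rand_protein(80)
    rows <- vapply(1:6, function(i) {
      v <- strsplit(anc, "", fixed = TRUE)[[1]]
      at <- sample(80, 25)
      v[at] <- vapply(at, function(k) sample(setdiff(AA20, v[k]), 1), "")
      paste(v, collapse = "")
    }, "")
    names(rows) <- paste0("s", 1:6)
  })
  msa <- proteinMSA(rows)
  kept <- vapply(c(0.3, 0.5, 0.7, 0.9), function(cf) {
    tr <- suppressWarnings(trimConservedBlocks(msa, consFrac = cf))
    if (nrow(tr$blocks)) sum(tr$blocks$end - tr$blocks$start) else 0L
  }, 0L)
  expect_true(all(diff(kept) <= 0L))
})
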