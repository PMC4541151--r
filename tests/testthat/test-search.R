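test_that("word index counts positions and skips words containing N", {
  db <- referenceDB(setNames(substr(paste(rep("ACGTG", 20), collapse = ""),
                                    1, 60), "r1"))
  idx <- buildWordIndex(db, 11L)
  expect_equal(idx$nIndexed, 60L - 11L + 1L)
  # one N removes the 11 windows covering it (here position 30)
  s <- as.character(refSequences(db))[1]
  substr(s, 30, 30) <- "N"
  idxN <- buildWordIndex(referenceDB(setNames(s, "r1")), 11L)
  expect_equal(idxN$nIndexed, 50L - 11L)
  expect_error(buildWordIndex(db, 61L), "r1")
})

test_that("a contig equal to a reference yields a full-length plus-strand self hit", {
  db <- make_random_db(5L, 500L)
  p <- searchParams()
  idx <- buildWordIndex(db, p@wordSize)
  for (i in c(1L, 4L)) {
    hits <- searchContig(as.character(refSequences(db)[[i]]), "q", idx, db, p)
    top <- hits[which.max(hits$raw_score), ]
    expect_equal(top$subject_id, names(db)[i])
    expect_equal(top$identity_pct, 100)
    expect_equal(top$align_len, 500L)
    expect_equal(top$strand, "+")
    expect_equal(c(top$q_start, top$q_end, top$s_start, top$s_end),
                 c(1L, 500L, 1L, 500L))
  }
})

test_that("reverse-complement queries return the same hit flagged minus", {
  db <- make_random_db(3L, 400L)
  p <- searchParams()
  idx <- buildWordIndex(db, p@wordSize)
  hits <- searchContig(revcomp(as.character(refSequences(db)[[2]])), "q",
                       idx, db, p)
  top <- hits[which.max(hits$raw_score), ]
  expect_equal(top$subject_id, names(db)[2])
  expect_equal(top$strand, "-")
  expect_equal(top$identity_pct, 100)
  expect_equal(c(top$q_start, top$q_end), c(1L, 400L))
})

test_that("strand involution: searching the reverse complement swaps strands and reflects coordinates", {
  withr::with_seed(7, {
    db <- make_random_db(2L, 300L, seed = 5L)
    gene <- as.character(refSequences(db)[[1]])
    contig <- paste0(rand_dna(80), gene, rand_dna(120))
  })
  p <- searchParams()
  idx <- buildWordIndex(db, p@wordSize)
  L <- nchar(contig)
  h1 <- searchContig(contig, "q", idx, db, p)
  h2 <- searchContig(revcomp(contig), "q", idx, db, p)
  h1 <- h1[order(h1$subject_id, h1$q_start), ]
  h2 <- h2[order(h2$subject_id, L - h2$q_end + 1L), ]
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(h2$strand, ifelse(h1$strand == "+", "-", "+"))
  expect_equal(L - h2$q_end + 1L, h1$q_start)
  expect_equal(L - h2$q_start + 1L, h1$q_end)
  expect_equal(h2$raw_score, h1$raw_score)
})

test_that("best hit raw score equals the Smith-Waterman optimum (Biostrings oracle)", {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -2,
                                                     baseOnly = TRUE)
  p <- searchParams()
  withr::with_seed(11, {
    for (rep in 1:15) {
      ref <- rand_dna(sample(100:300, 1))
      mut <- mutateSequence(ref, sample(c(85, 92, 98), 1), seed = rep)
      contig <- paste0(rand_dna(40), mut, rand_dna(40))
      if (rep %% 2 == 0) contig <- revcomp(contig)
      db <- referenceDB(setNames(ref, "r1"))
      hits <- searchContig(contig, "q", buildWordIndex(db, 11L), db, p)
      sw <- Biostrings::pairwiseAlignment(contig, ref, type = "local",
                                          substitutionMatrix = submat,
                                          gapOpening = 5, gapExtension = 2)
      swrc <- Biostrings::pairwiseAlignment(revcomp(contig), ref,
                                            type = "local",
                                            substitutionMatrix = submat,
                                            gapOpening = 5,
                                            gapExtension = 2)
      expect_equal(max(hits$raw_score),
                   max(Biostrings::score(sw), Biostrings::score(swrc)))
    }
  })
})

test_that("contigs shorter than the word size warn and return no hits", {
  db <- make_random_db(1L, 100L)
  idx <- buildWordIndex(db, 11L)
  expect_warning(h <- searchContig("ACGTACGT", "tiny", idx, db,
                                   searchParams()),
                 "shorter than word size")
  expect_equal(nrow(h), 0L)
})

test_that("filters enforce the 40 bp threshold inclusively and the E-value cutoff", {
  h <- .make_hit_row(align_len = 39L, evalue = 1e-9)
  h <- rbind(h, .make_hit_row(align_len = 40L, evalue = 1e-5),
             .make_hit_row(align_len = 400L, evalue = 1e-3))
  p <- searchParams()
  f <- filterHits(h, p)
  expect_equal(f$align_len, 40L) # 39 bp fails length; 1e-3 fails E-value
  expect_equal(nrow(filterHits(h[0, ], p)), 0L)
})

test_that("filtered hits sort by length desc, then E-value, then subject", {
  h <- rbind(.make_hit_row(align_len = 50L, evalue = 1e-9, subject = "b"),
             .make_hit_row(align_len = 80L, evalue = 1e-6, subject = "c"),
             .make_hit_row(align_len = 50L, evalue = 1e-12, subject = "a"))
  f <- filterHits(h, searchParams())
  expect_equal(f$subject_id, c("c", "a", "b"))
})

test_that("candidate contigs are the unique query ids of surviving hits", {
  h <- rbind(.make_hit_row(query = "c1"), .make_hit_row(query = "c1"),
             .make_hit_row(query = "c2"))
  expect_setequal(candidateContigs(h), c("c1", "c2"))
  expect_length(candidateContigs(h[0, ]), 0L)
})

test_that("hits survive a tabular write/read round trip including strand", {
  db <- make_random_db(2L, 300L)
  contig <- paste0(rand_dna(30), revcomp(as.character(refSequences(db)[[1]])),
                   rand_dna(30))
  p <- searchParams()
  hits <- searchContig(contig, "q1", buildWordIndex(db), db, p)
  path <- tempfile(fileext = ".tsv")
  writeHitsTSV(hits, path)
  back <- readHitsTSV(path)
  expect_equal(back$query_id, hits$query_id)
  expect_equal(back$subject_id, hits$subject_id)
  expect_equal(back$strand, hits$strand)
  expect_equal(back$q_start, hits$q_start)
  expect_equal(back$s_start, hits$s_start)
  expect_equal(ncol(utils::read.table(path, sep = "\t")), 12L)
})
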