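small_cfg <- function(seed = 7L)
  simConfig(nAtpase = 4L, nMco = 4L, geneLenRange = c(450L, 750L),
            nGeneContigs = 3L, nDecoyContigs = 4L,
            contigLenRange = c(900L, 1500L), seed = seed)

test_that("reference generation is byte-identical under a fixed seed", {
  r1 <- generateReferenceSet(small_cfg())
  r2 <- generateReferenceSet(small_cfg())
  expect_identical(as.character(refSequences(r1$db)),
                   as.character(refSequences(r2$db)))
  expect_identical(r1$proteins, r2$proteins)
  r3 <- generateReferenceSet(small_cfg(seed = 8L))
  expect_false(identical(as.character(refSequences(r1$db)),
                         as.character(refSequences(r3$db))))
})

test_that("generated genes carry their motifs and no internal stops", {
  rs <- generateReferenceSet(small_cfg())
  groups <- refGroups(rs$db)
  for (id in names(rs$proteins)) {
    prot <- rs$proteins[[id]]
    expect_false(grepl("*", prot, fixed = TRUE))
    hits <- scanMotifs(prot, defaultMotifSet())
    if (groups[[id]] == "ATPASE") {
      expect_gte(sum(hits$pattern_name == "CPC"), 1L)
      expect_gte(sum(hits$pattern_name == "GDGIN"), 1L)
    } else {
      expect_gte(length(unique(hits$start[hits$pattern_name == "HXH"])), 2L)
    }
    nt <- as.character(refSequences(rs$db)[[id]])
    expect_equal(substr(nt, 1, 3), "ATG")
    expect_true(substr(nt, nchar(nt) - 2, nchar(nt)) %in%
                  c("TAA", "TAG", "TGA"))
    # translation round trip: protein encoded exactly
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(substr(nt, 1, nchar(nt) - 3)),
      genetic.code = Biostrings::getGeneticCode("11")))
    expect_equal(unname(aa), prot)
  }
})

test_that("every generated protein passes its own group's default screen", {
  rs <- generateReferenceSet(small_cfg())
  groups <- refGroups(rs$db)
  ms <- defaultMotifSet()
  for (id in names(rs$proteins)) {
    hits <- scanMotifs(rs$proteins[[id]], ms)
    call <- functionalScreen(rs$proteins[[id]], groups[[id]], hits)
    expect_equal(call$functional_call, "HIGH_POTENTIAL")
  }
})

test_that("mutation reaches the identity target within one point, motifs intact", {
  rs <- generateReferenceSet(small_cfg())
  id <- names(rs$proteins)[1]
  gene <- as.character(refSequences(rs$db)[[id]])
  expect_identical(mutateSequence(gene, 100, rs$motifNt[[id]], seed = 3L),
                   gene)
  for (target in c(95, 85, 75)) {
    mut <- mutateSequence(gene, target, rs$motifNt[[id]], seed = 3L)
    expect_equal(nchar(mut), nchar(gene))
    ident <- 100 * mean(strsplit(mut, "")[[1]] == strsplit(gene, "")[[1]])
    expect_lte(abs(ident - target), 1)
    # protected motif codons survive, so the translated motifs are intact
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(substr(mut, 1, nchar(mut) - 3)),
      genetic.code = Biostrings::getGeneticCode("11"),
      if.fuzzy.codon = "X"))
    expect_false(grepl("*", aa, fixed = TRUE)) # no premature stop
    hits <- scanMotifs(aa, defaultMotifSet())
    expect_gte(sum(hits$pattern_name == "CPC"), 1L)
    expect_gte(sum(hits$pattern_name == "GDGIN"), 1L)
  }
})

test_that("over-constrained mutation targets are rejected", {
  gene <- paste(rep("ATGGCG", 20), collapse = "")
  expect_error(mutateSequence(gene, 55, protect = seq_len(100L), seed = 1L),
               "unreachable")
  expect_error(mutateSequence(gene, 40), "must be in")
})

test_that("planting embeds genes recoverably on the recorded strand and offset", {
  cfg <- small_cfg()
  rs <- generateReferenceSet(cfg)
  ids <- names(rs$proteins)[1:3]
  genes <- setNames(as.character(refSequences(rs$db)[ids]),
                    paste0("g", 1:3))
  planted <- plantInContigs(genes, cfg)
  expect_equal(length(planted$contigs), 3L + cfg$nDecoyContigs)
  expect_equal(nrow(planted$truth), 3L)
  expect_equal(length(planted$decoy_ids), cfg$nDecoyContigs)
  for (i in 1:3) {
    tr <- planted$truth[i, ]
    frag <- substr(as.character(planted$contigs[[tr$contig_id]]),
                   tr$start + 1L, tr$end)
    if (tr$strand == "-") frag <- revcomp(frag)
    expect_identical(frag, unname(genes[tr$gene_id]))
  }
  # reproducible under the seed
  planted2 <- plantInContigs(genes, cfg)
  expect_identical(as.character(planted$contigs),
                   as.character(planted2$contigs))
  # no genes: only decoys, empty truth
  p0 <- plantInContigs(character(0), cfg)
  expect_equal(nrow(p0$truth), 0L)
  expect_equal(length(p0$contigs), cfg$nDecoyContigs)
})

test_that("recovery metrics follow hand counts", {
  truth <- data.frame(contig_id = c("c1", "c2"), gene_id = c("g1", "g2"),
                      start = c(100L, 200L), end = c(400L, 800L),
                      strand = c("+", "-"), source_ref = "r",
                      target_identity_pct = 100, motifs_intact = TRUE,
                      stringsAsFactors = FALSE)
  rec_half <- data.frame(contig_id = "c1", start = 90L, end = 410L,
                         strand = "+", stringsAsFactors = FALSE)
  m <- evaluateRecovery(truth, rec_half, decoyIds = c("d1", "d2"))
  expect_equal(m$sensitivity$value, 50)
  expect_equal(m$sensitivity$numerator, 1L)
  expect_equal(m$specificity$value, 100)
  # empty recovered set: sensitivity 0, specificity 100
  m0 <- evaluateRecovery(truth, rec_half[0, ], decoyIds = c("d1", "d2"))
  expect_equal(m0$sensitivity$value, 0)
  expect_equal(m0$specificity$value, 100)
  # a recovered gene on a decoy lowers specificity
  bad <- rbind(rec_half, data.frame(contig_id = "d1", start = 0L,
                                    end = 300L, strand = "+"))
  m2 <- evaluateRecovery(truth, bad, decoyIds = c("d1", "d2"))
  expect_equal(m2$specificity$value, 50)
  # empty truth: sensitivity undefined with a warning
  expect_warning(m3 <- evaluateRecovery(truth[0, ], rec_half,
                                        decoyIds = "d1"),
                 "undefined")
  expect_true(is.na(m3$sensitivity$value))
  # strand mismatches never count as true positives
  flipped <- rec_half
  flipped$strand <- "-"
  m4 <- evaluateRecovery(truth, flipped, decoyIds = "d1")
  expect_equal(m4$sensitivity$value, 0)
})

test_that("planting the database's own genes reproduces perfect self-identification", {
  cfg <- small_cfg(seed = 19L)
  sim <- simulateMetagenome(cfg, targetIdentity = 100)
  params <- searchParams()
  f <- filterHits(searchContigs(sim$contigs, sim$db, params), params)
  orfs <- do.call(rbind, lapply(candidateContigs(f), function(id)
    findOrfs(as.character(sim$contigs[[id]]), id, 300L)))
  rec <- mapHitsToOrfs(f, orfs)
  cur <- curateCandidates(rec$genes, sim$db, 70)
  m <- evaluateRecovery(sim$truth, cur, sim$decoy_ids)
  expect_equal(m$sensitivity$value, 100)
  expect_equal(m$specificity$value, 100)
})
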