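test_that("the default motif set matches the published screening alphabet", {
  ms <- defaultMotifSet()
  expect_false(anyDuplicated(ms$name) > 0)
  expect_equal(ms$category[ms$name == "GDGIN"], "ATP_BINDING")
  expect_true(all(c("CPC", "YPC") %in% ms$name[ms$group == "ATPASE"]))
  expect_equal(ms$group[ms$name == "HXH"], "MCO")
  expect_true(all(nchar(ms$pattern) >= 3))
})

test_that("literal and wildcard patterns hit hand-checked positions", {
  hits <- scanMotifs("MKCPCAG", defaultMotifSet())
  expect_equal(hits$start[hits$pattern_name == "CPC"], 3L)
  hits2 <- scanMotifs("ACDDCA", defaultMotifSet())
  expect_equal(hits2$matched_text[hits2$pattern_name == "CXXC"], "CDDC")
  expect_equal(hits2$start[hits2$pattern_name == "CXXC"], 2L)
})

test_that("overlapping occurrences are all reported and query X never matches", {
  hits <- scanMotifs("HAHAH", defaultMotifSet())
  expect_equal(hits$start[hits$pattern_name == "HXH"], c(1L, 3L))
  # X in the query fails the wildcard position
  expect_equal(nrow(scanMotifs("CXC", defaultMotifSet()[
    defaultMotifSet()$name == "CPC", , drop = FALSE])), 0L)
  hits3 <- scanMotifs("HXH", defaultMotifSet())
  expect_equal(nrow(hits3[hits3$pattern_name == "HXH", ]), 0L)
})

test_that("the scanner agrees with the naive sliding-window oracle", {
  ms <- defaultMotifSet()
  withr::with_seed(51, {
    for (p in seq_len(nrow(ms))) {
      for (rep in 1:40) {
        # enriched alphabet so motif letters occur often
        aa <- paste(sample(c(AA20, strsplit(ms$pattern[p], "")[[1]],
                             "C", "H", "P", "X"), 60, TRUE), collapse = "")
        aa <- gsub("X{2,}", "X", aa)
        mine <- scanMotifs(aa, ms[p, , drop = FALSE])$start
        expect_equal(mine, oracle_scan(aa, ms$pattern[p]))
      }
    }
  })
})

test_that("candidate positions map through the reference gap structure", {
  ref_row <- "MK--VLITAH"
  msa <- proteinMSA(c(ref = ref_row, other = "MKAAVLITAH"))
  # identical candidate: identity mapping onto the reference's columns
  map <- mapToReferenceAlignment("MKVLITAH", "ref", msa)
  expect_equal(map, c(1L, 2L, 5L, 6L, 7L, 8L, 9L, 10L))
  expect_error(mapToReferenceAlignment("MKVLITAH", "absent", msa),
               "not a row")
})

test_that("candidate deletions shift downstream positions; insertions map to NA", {
  ref_row <- "MKVLITAHAC"
  msa <- proteinMSA(c(ref = ref_row, other = "MKVLITAHAC"))
  # candidate missing VL: downstream residues still map to their columns
  map_del <- mapToReferenceAlignment("MKITAHAC", "ref", msa)
  expect_equal(map_del, c(1L, 2L, 5L, 6L, 7L, 8L, 9L, 10L))
  # candidate with an internal insertion relative to the reference
  map_ins <- mapToReferenceAlignment("MKVLWWWITAHAC", "ref", msa)
  expect_equal(map_ins[1:4], 1:4)
  expect_true(anyNA(map_ins[5:7]))
  expect_equal(map_ins[8:13], 5:10)
})

test_that("group classification follows the nearest labeled reference", {
  db <- make_random_db(3L)
  db <- assignGroups(db, setNames(c("ATPASE", "MCO"), names(db)[1:2]))
  gene <- data.frame(best_subject = names(db)[1])
  expect_equal(classifyGroup(gene, db), "ATPASE")
  expect_equal(classifyGroup(data.frame(best_subject = names(db)[3]), db),
               "UNKNOWN")
  expect_equal(classifyGroup(data.frame(best_subject = NA_character_), db),
               "UNKNOWN")
})

test_that("identity ties between groups resolve deterministically by record id", {
  orfs <- data.frame(contig_id = "c1", start = 0L, end = 600L,
                     strand = "+", frame = 0L, nt = "N", aa = "X",
                     stringsAsFactors = FALSE)
  h <- rbind(.make_hit_row(query = "c1", subject = "gi_2_zz", identity = 88),
             .make_hit_row(query = "c1", subject = "gi_1_aa", identity = 88))
  res <- mapHitsToOrfs(h, orfs)
  expect_equal(res$genes$best_subject, "gi_1_aa")
})

test_that("the functional screen applies the published rule set", {
  ms <- defaultMotifSet()
  atp_ok <- scanMotifs(paste0(rand_protein(20), "CPC", rand_protein(30),
                              "GDGIN", rand_protein(10)), ms)
  expect_equal(functionalScreen("x", "ATPASE", atp_ok)$functional_call,
               "HIGH_POTENTIAL")
  # YPC substitutes for CPC
  ypc <- scanMotifs(paste0("AAYPCAA", "GDGIN"), ms)
  expect_equal(functionalScreen("x", "ATPASE", ypc)$functional_call,
               "HIGH_POTENTIAL")
  # missing GDGIN fails the ATPase rule even with CXXC present
  no_atp <- scanMotifs("AACDDCAACPCAA", ms)
  expect_equal(functionalScreen("x", "ATPASE", no_atp)$functional_call,
               "INSUFFICIENT_EVIDENCE")
  # MCO needs two distinct HXH sites
  one_hxh <- scanMotifs("AAHGHAA", ms)
  expect_equal(functionalScreen("x", "MCO", one_hxh)$functional_call,
               "INSUFFICIENT_EVIDENCE")
  two_hxh <- scanMotifs("AAHGHAAHSHAA", ms)
  expect_equal(functionalScreen("x", "MCO", two_hxh)$functional_call,
               "HIGH_POTENTIAL")
  # UNKNOWN group never passes
  expect_equal(functionalScreen("x", "UNKNOWN", two_hxh)$functional_call,
               "INSUFFICIENT_EVIDENCE")
  # empty match set never passes
  none <- scanMotifs("AAA", ms)
  expect_equal(functionalScreen("x", "ATPASE", none)$functional_call,
               "INSUFFICIENT_EVIDENCE")
})

test_that("screening is pure and monotone in the match set", {
  ms <- defaultMotifSet()
  seq <- paste0("AACPCAA", "GDGIN", "AA")
  m1 <- scanMotifs(seq, ms)
  r1 <- functionalScreen(seq, "ATPASE", m1)
  r2 <- functionalScreen(seq, "ATPASE", m1)
  expect_identical(r1, r2)
  # adding matches never demotes the call
  extra <- rbind(m1, data.frame(pattern_name = "CXXC", start = 50L,
                                matched_text = "CAAC"))
  expect_equal(functionalScreen(seq, "ATPASE", extra)$functional_call,
               "HIGH_POTENTIAL")
})
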