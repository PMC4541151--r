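# Synthetic planted-gene benchmark: motif-bearing reference families,
# identity-controlled mutated variants, planted-gene contig sets with truth
# tables, and sensitivity/specificity evaluation of the recovery pipeline.

#' Simulation configuration
#'
#' Defaults describe the benchmark conditions used throughout: a 20-gene
#' two-family reference database, 20 planted-gene contigs and 50 decoy
#' contigs of 2-5 kb at 62% GC (the GC content of the tailings metagenome
#' libraries this benchmark emulates), with planted-gene identities dialed
#' over 95/85/75/65%.
#'
#' @param nAtpase,nMco Genes per family.
#' @param geneLenRange Gene length range in bp (multiples of 3 are drawn).
#' @param nGeneContigs,nDecoyContigs Contigs with and without planted genes.
#' @param contigLenRange Contig length range in bp.
#' @param identityLevels Target nucleotide identity levels (percent, in
#'   (50, 100]).
#' @param gcContent Background GC fraction.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A `SimConfig` list.
#' @export
simConfig <- function(nAtpase = 10L, nMco = 10L,
                      geneLenRange = c(900L, 1800L),
                      nGeneContigs = 20L, nDecoyContigs = 50L,
                      contigLenRange = c(2000L, 5000L),
                      identityLevels = c(95, 85, 75, 65),
                      gcContent = 0.62, seed = 1L) {
  stopifnot(nAtpase >= 0L, nMco >= 0L, nGeneContigs >= 0L,
            nDecoyContigs >= 0L, gcContent > 0, gcContent < 1,
            all(identityLevels > 50), all(identityLevels <= 100),
            geneLenRange[1L] <= geneLenRange[2L],
            contigLenRange[1L] <= contigLenRange[2L])
  structure(list(nAtpase = as.integer(nAtpase), nMco = as.integer(nMco),
                 geneLenRange = as.integer(geneLenRange),
                 nGeneContigs = as.integer(nGeneContigs),
                 nDecoyContigs = as.integer(nDecoyContigs),
                 contigLenRange = as.integer(contigLenRange),
                 identityLevels = identityLevels, gcContent = gcContent,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# codon table for back-translation (bacterial table 11 codon assignments)
.codons_by_aa <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::getGeneticCode("11")
      cache <<- split(names(gc), gc)
    }
    cache
  }
})

.random_protein <- function(len) {
  paste(sample(.aa_alphabet(), len, replace = TRUE), collapse = "")
}

.back_translate <- function(aa) {
  tab <- .codons_by_aa()
  codons <- vapply(strsplit(aa, "", fixed = TRUE)[[1L]], function(a) {
    opts <- tab[[a]]
    opts <- setdiff(opts, c("TAA", "TAG", "TGA"))
    opts[sample.int(length(opts), 1L)]
  }, "")
  codons[1L] <- "ATG" # enforce canonical start
  paste(c(codons, sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
}

# place a motif string into a protein at aa position pos (1-based)
.place_motif <- function(aa, motif, pos) {
  substr(aa, pos, pos + nchar(motif) - 1L) <- motif
  aa
}

#' Generate a two-family motif-bearing reference set
#'
#' Each family descends from a random ancestor protein carrying the family
#' motifs: ATPASE ancestors carry CXXC (realized as CAAC), CPC and GDGIN;
#' MCO ancestors carry two HXH sites. Members derive from the ancestor by
#' random residue substitution away from motif positions (15% per member),
#' with the N-terminal CXXC additionally ablated in roughly half of the
#' ATPASE members; members are then back-translated independently with
#' random synonymous codons, an ATG start and a random stop. Output is
#' deterministic under `cfg$seed`.
#'
#' @param cfg A [simConfig()].
#' @return List with `db` (a group-labeled [ReferenceDB]), `proteins`
#'   (named character, one per gene), `motifAa` (per-gene list of 1-based
#'   motif residue positions) and `motifNt` (per-gene integer vector of
#'   protected nucleotide positions: motif codons plus start and stop).
#' @export
generateReferenceSet <- function(cfg) {
  if (cfg$nAtpase + cfg$nMco < 2L)
    .stopf("need at least 2 reference genes")
  .with_seed(cfg$seed, {
    proteins <- character(0)
    groups <- character(0)
    motifAa <- list()
    gene_i <- 0L
    for (fam in c("ATPASE", "MCO")) {
      n_mem <- if (fam == "ATPASE") cfg$nAtpase else cfg$nMco
      if (n_mem == 0L) next
      nt_len <- 3L * (sample(seq(cfg$geneLenRange[1L] %/% 3L,
                                 cfg$geneLenRange[2L] %/% 3L), 1L))
      aa_len <- nt_len %/% 3L - 1L
      if (aa_len < 30L) .stopf("gene length range too short for motifs")
      anc <- .random_protein(aa_len)
      substr(anc, 1L, 1L) <- "M"
      if (fam == "ATPASE") {
        sites <- list(CXXC = 8L,
                      CPC = max(20L, round(aa_len * 0.4)),
                      GDGIN = max(26L, round(aa_len * 0.7)))
        anc <- .place_motif(anc, "CAAC", sites$CXXC)
        anc <- .place_motif(anc, "CPC", sites$CPC)
        anc <- .place_motif(anc, "GDGIN", sites$GDGIN)
        motif_pos <- c(sites$CXXC + 0:3, sites$CPC + 0:2, sites$GDGIN + 0:4)
        motif_map <- list(CXXC = sites$CXXC + 0:3, CPC = sites$CPC + 0:2,
                          GDGIN = sites$GDGIN + 0:4)
      } else {
        sites <- list(HXH1 = max(10L, round(aa_len * 0.3)),
                      HXH2 = max(16L, round(aa_len * 0.6)))
        anc <- .place_motif(anc, "HGH", sites$HXH1)
        anc <- .place_motif(anc, "HSH", sites$HXH2)
        motif_pos <- c(sites$HXH1 + 0:2, sites$HXH2 + 0:2)
        motif_map <- list(HXH1 = sites$HXH1 + 0:2, HXH2 = sites$HXH2 + 0:2)
      }
      for (m in seq_len(n_mem)) {
        gene_i <- gene_i + 1L
        aa <- strsplit(anc, "", fixed = TRUE)[[1L]]
        free <- setdiff(2:aa_len, motif_pos)
        n_sub <- round(0.15 * length(free))
        at <- sample(free, n_sub)
        aa[at] <- vapply(aa[at], function(old)
          sample(setdiff(.aa_alphabet(), old), 1L), "")
        mem_map <- motif_map
        if (fam == "ATPASE" && runif(1) < 0.5) {
          # ablate the optional N-terminal CXXC in this member
          cx <- motif_map$CXXC
          aa[cx[c(1L, 4L)]] <- vapply(aa[cx[c(1L, 4L)]], function(old)
            sample(setdiff(.aa_alphabet(), c("C", old)), 1L), "")
          mem_map$CXXC <- NULL
        }
        prot <- paste(aa, collapse = "")
        id <- sprintf("gi_%09d_%s_sp%02d", 100000000L + gene_i,
                      if (fam == "ATPASE") "Synthetibacter" else
                        "Syntheticoccus", gene_i)
        proteins[id] <- prot
        groups[id] <- fam
        motifAa[[id]] <- mem_map
      }
    }
    genes <- vapply(proteins, .back_translate, "")
    motifNt <- lapply(names(genes), function(id) {
      aapos <- unlist(motifAa[[id]], use.names = FALSE)
      nt <- as.integer(outer(1:3, (aapos - 1L) * 3L, "+"))
      sort(unique(c(1:3, nt, nchar(genes[[id]]) - 2:0)))
    })
    names(motifNt) <- names(genes)
    db <- referenceDB(genes, name = "synthetic_refdb")
    db <- assignGroups(db, groups)
    list(db = db, proteins = proteins, motifAa = motifAa, motifNt = motifNt)
  })
}

.is_stop_codon <- function(codon) codon %in% c("TAA", "TAG", "TGA")

#' Mutate a gene to a target nucleotide identity
#'
#' Applies random substitutions (no indels) until the identity to the
#' original is within one percentage point of `targetIdentityPct`.
#' Positions listed in `protect` (typically motif codons plus start/stop
#' from [generateReferenceSet()]) are exempt, and a substitution that would
#' create an in-frame stop codon is re-drawn — planted genes model
#' functional full-length coding sequences, so premature stops are excluded
#' (purifying selection on the reading frame). Deterministic under `seed`.
#'
#' @param gene Nucleotide sequence (character).
#' @param targetIdentityPct Target identity in (50, 100].
#' @param protect Integer vector of 1-based protected positions.
#' @param seed Integer seed.
#' @return The mutated sequence.
#' @export
mutateSequence <- function(gene, targetIdentityPct, protect = integer(0),
                           seed = 1L) {
  if (targetIdentityPct <= 50 || targetIdentityPct > 100)
    .stopf("target identity must be in (50, 100]")
  gene <- toupper(as.character(gene))
  L <- nchar(gene)
  k <- round((100 - targetIdentityPct) / 100 * L)
  if (k == 0L) return(gene)
  protect <- sort(unique(c(as.integer(protect), 1:3, (L - 2L):L)))
  allowed <- setdiff(seq_len(L), protect)
  k_min <- ceiling((100 - targetIdentityPct - 1) * L / 100)
  if (length(allowed) < k_min)
    .stopf(paste0("target identity %.1f%% unreachable: only %d of %d ",
                  "positions are mutable under motif protection"),
           targetIdentityPct, length(allowed), L)
  .with_seed(seed, {
    v <- strsplit(gene, "", fixed = TRUE)[[1L]]
    queue <- sample(allowed)
    n_done <- 0L
    for (pos in queue) {
      if (n_done >= k) break
      codon_start <- ((pos - 1L) %/% 3L) * 3L + 1L
      codon <- v[codon_start:(codon_start + 2L)]
      alt <- setdiff(DNA_BASES4, v[pos])
      alt <- sample(alt)
      placed <- FALSE
      for (b in alt) {
        cand <- codon
        cand[pos - codon_start + 1L] <- b
        if (!.is_stop_codon(paste(cand, collapse = ""))) {
          v[pos] <- b
          placed <- TRUE
          break
        }
      }
      if (placed) n_done <- n_done + 1L
    }
    if (n_done < k_min)
      .stopf("could not reach target identity %.1f%% (placed %d of %d)",
             targetIdentityPct, n_done, k)
    paste(v, collapse = "")
  })
}

.random_background <- function(len, gc) {
  paste(sample(DNA_BASES4, len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Plant genes into random-background contigs
#'
#' Each gene is embedded at a uniform random offset, on a uniform random
#' strand, in an i.i.d. background contig matching `cfg$gcContent`; decoy
#' contigs contain no planted gene. Deterministic under `cfg$seed` (offset
#' by one so the generator and the planter draw independent streams).
#'
#' @param genes Named character vector of gene sequences to plant (one
#'   contig each).
#' @param cfg A [simConfig()]; `nDecoyContigs` and `contigLenRange` apply.
#' @param meta Optional data.frame aligned with `genes` providing
#'   `source_ref`, `target_identity_pct`, `motifs_intact` for the truth
#'   table.
#' @return List with `contigs` (named [Biostrings::DNAStringSet]), `truth`
#'   (data.frame: contig_id, gene_id, start, end — 0-based half-open —,
#'   strand, source_ref, target_identity_pct, motifs_intact) and
#'   `decoy_ids`.
#' @export
plantInContigs <- function(genes, cfg, meta = NULL) {
  .with_seed(cfg$seed + 1L, {
    contigs <- character(0)
    truth <- NULL
    for (i in seq_along(genes)) {
      glen <- nchar(genes[[i]])
      clen <- max(glen + 20L,
                  sample(seq(cfg$contigLenRange[1L], cfg$contigLenRange[2L]),
                         1L))
      offset <- sample.int(clen - glen + 1L, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      insert <- if (strand == "+") genes[[i]] else .revcomp(genes[[i]])
      bg <- .random_background(clen, cfg$gcContent)
      contig <- paste0(substr(bg, 1L, offset), insert,
                       substr(bg, offset + glen + 1L, clen))
      cid <- sprintf("contig_%03d", i)
      contigs[cid] <- contig
      truth <- rbind(truth, data.frame(
        contig_id = cid, gene_id = names(genes)[i],
        start = offset, end = offset + glen, strand = strand,
        source_ref = if (!is.null(meta)) meta$source_ref[i] else
          names(genes)[i],
        target_identity_pct = if (!is.null(meta))
          meta$target_identity_pct[i] else 100,
        motifs_intact = if (!is.null(meta)) meta$motifs_intact[i] else TRUE,
        stringsAsFactors = FALSE))
    }
    decoy_ids <- character(0)
    for (d in seq_len(cfg$nDecoyContigs)) {
      clen <- sample(seq(cfg$contigLenRange[1L], cfg$contigLenRange[2L]), 1L)
      did <- sprintf("decoy_%03d", d)
      contigs[did] <- .random_background(clen, cfg$gcContent)
      decoy_ids <- c(decoy_ids, did)
    }
    if (is.null(truth))
      truth <- data.frame(contig_id = character(), gene_id = character(),
                          start = integer(), end = integer(),
                          strand = character(), source_ref = character(),
                          target_identity_pct = numeric(),
                          motifs_intact = logical(),
                          stringsAsFactors = FALSE)
    list(contigs = Biostrings::DNAStringSet(contigs), truth = truth,
         decoy_ids = decoy_ids)
  })
}

.jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0L, min(e1, e2) - max(s1, s2))
  union <- (e1 - s1) + (e2 - s2) - inter
  if (union <= 0L) 0 else inter / union
}

#' Evaluate recovered genes against the planted truth
#'
#' A recovered gene is a true positive when it overlaps a truth interval on
#' the same contig and strand with interval Jaccard at least `minJaccard`
#' (each truth record matches at most one recovered gene). Sensitivity is
#' TP over planted genes, precision TP over recovered genes, specificity
#' the fraction of decoy contigs carrying no recovered gene.
#'
#' @param truth Truth table from [plantInContigs()].
#' @param recovered Recovered genes data.frame (from [mapHitsToOrfs()] or
#'   [curateCandidates()]).
#' @param decoyIds Character vector of decoy contig ids.
#' @param minJaccard True-positive overlap threshold (default 0.5).
#' @return List of metrics, each with value (percent; NA when undefined,
#'   with a warning for an empty truth set), numerator and denominator.
#' @export
evaluateRecovery <- function(truth, recovered, decoyIds,
                             minJaccard = 0.5) {
  matched_truth <- rep(FALSE, nrow(truth))
  matched_rec <- rep(FALSE, nrow(recovered))
  if (nrow(truth) && nrow(recovered)) {
    pairs <- NULL
    for (t in seq_len(nrow(truth))) {
      for (r in seq_len(nrow(recovered))) {
        if (truth$contig_id[t] != recovered$contig_id[r]) next
        if (truth$strand[t] != recovered$strand[r]) next
        j <- .jaccard(truth$start[t], truth$end[t],
                      recovered$start[r], recovered$end[r])
        if (j >= minJaccard) pairs <- rbind(pairs, c(t, r, j))
      }
    }
    if (!is.null(pairs)) {
      pairs <- pairs[order(-pairs[, 3L]), , drop = FALSE]
      for (p in seq_len(nrow(pairs))) {
        t <- pairs[p, 1L]; r <- pairs[p, 2L]
        if (!matched_truth[t] && !matched_rec[r]) {
          matched_truth[t] <- TRUE
          matched_rec[r] <- TRUE
        }
      }
    }
  }
  tp <- sum(matched_truth)
  if (nrow(truth) == 0L)
    .warnf("empty truth set: sensitivity is undefined")
  sens <- if (nrow(truth)) 100 * tp / nrow(truth) else NA_real_
  prec <- if (nrow(recovered)) 100 * sum(matched_rec) / nrow(recovered)
    else NA_real_
  clean_decoys <- sum(!decoyIds %in% recovered$contig_id)
  spec <- if (length(decoyIds)) 100 * clean_decoys / length(decoyIds)
    else NA_real_
  list(sensitivity = list(value = sens, numerator = tp,
                          denominator = nrow(truth)),
       precision = list(value = prec, numerator = sum(matched_rec),
                        denominator = nrow(recovered)),
       specificity = list(value = spec, numerator = clean_decoys,
                          denominator = length(decoyIds)))
}

#' Simulate a planted-gene metagenome end to end
#'
#' Generates the reference set, draws `cfg$nGeneContigs` member genes (with
#' replacement), mutates each to `targetIdentity` with motif codons
#' protected, and plants them among decoy contigs.
#'
#' @param cfg A [simConfig()].
#' @param targetIdentity Single identity target in percent (100 = plant
#'   unmutated copies).
#' @return List with `db`, `refset`, `contigs`, `truth`, `decoy_ids`.
#' @export
simulateMetagenome <- function(cfg, targetIdentity = 85) {
  refset <- generateReferenceSet(cfg)
  ids <- .with_seed(cfg$seed + 2L,
                    sample(names(refset$db@seqs), cfg$nGeneContigs,
                           replace = TRUE))
  genes <- character(0)
  meta <- NULL
  for (i in seq_along(ids)) {
    src <- ids[i]
    seq0 <- as.character(refset$db@seqs[[src]])
    mut <- if (targetIdentity >= 100) seq0 else
      mutateSequence(seq0, targetIdentity, refset$motifNt[[src]],
                     seed = cfg$seed + 100L + i)
    gid <- sprintf("planted_%03d", i)
    genes[gid] <- mut
    meta <- rbind(meta, data.frame(source_ref = src,
                                   target_identity_pct = targetIdentity,
                                   motifs_intact = TRUE,
                                   stringsAsFactors = FALSE))
  }
  planted <- plantInContigs(genes, cfg, meta)
  c(list(db = refset$db, refset = refset), planted)
}
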