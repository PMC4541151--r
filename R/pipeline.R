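# End-to-end orchestration: build-db -> search -> filter -> recover ->
# curate -> screen -> tree/report. Stages communicate via on-disk artifacts
# in out_dir so any stage can be rerun in isolation.

#' Default pipeline configuration
#'
#' @param contigs,db Paths to the contig FASTA and reference database FASTA.
#' @param outDir Output directory (created if missing).
#' @param groups Optional path to a record_id/group TSV (see
#'   [readGroupLabels()]).
#' @param refTree Optional newick tree (e.g. 16S-based) for congruence.
#' @param search Named list overriding [searchParams()] arguments.
#' @param minOrfLen Minimum ORF length in nt.
#' @param minIdentityPct Curation identity cutoff (percent).
#' @param mcoMinHxh MCO screening rule threshold.
#' @param buildTree Build an NJ tree of curated gene proteins (3-40 genes).
#' @param seed Seed echoed into the report (the pipeline itself is
#'   deterministic).
#' @return A `PipelineConfig` list.
#' @export
pipelineConfig <- function(contigs, db, outDir, groups = NULL,
                           refTree = NULL, search = list(),
                           minOrfLen = 300L, minIdentityPct = 70,
                           mcoMinHxh = 2L, buildTree = TRUE, seed = 1L) {
  structure(list(contigs = contigs, db = db, outDir = outDir,
                 groups = groups, refTree = refTree, search = search,
                 minOrfLen = minOrfLen, minIdentityPct = minIdentityPct,
                 mcoMinHxh = mcoMinHxh, buildTree = buildTree,
                 seed = seed),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipelineConfig()] (snake_case
#' accepted).
#'
#' @param path YAML path.
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  nm <- names(y)
  names(y)[nm == "out_dir"] <- "outDir"
  names(y)[nm == "ref_tree"] <- "refTree"
  names(y)[nm == "min_orf_len"] <- "minOrfLen"
  names(y)[nm == "min_identity_pct"] <- "minIdentityPct"
  names(y)[nm == "mco_min_hxh"] <- "mcoMinHxh"
  names(y)[nm == "build_tree"] <- "buildTree"
  do.call(pipelineConfig, y)
}

.log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

.run_stage <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e)
    .stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  list(result = res, elapsed = proc.time()[["elapsed"]] - t0)
}

#' Run the full recovery pipeline
#'
#' Executes database validation, seeded search, screening filters, ORF-based
#' recovery, identity curation, motif screening and (optionally) an NJ tree
#' of the curated gene proteins. Every intermediate is written to
#' `cfg$outDir`; the returned run report echoes parameters and per-stage
#' counts, which are non-increasing along the filter chain (hits >= filtered
#' hits; recovered >= curated >= high-potential).
#'
#' @param cfg A `PipelineConfig` from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @return The run report (list), also written to `out_dir/report.json`.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(tool = "copAminer",
                 version = as.character(packageVersion("copAminer")),
                 seed = cfg$seed, params = cfg[setdiff(names(cfg),
                                                       c("outDir"))],
                 counts = list(), elapsed = list())

  st <- .run_stage("build-db", {
    if (!file.exists(cfg$db)) .stopf("missing db path '%s'", cfg$db)
    if (!file.exists(cfg$contigs))
      .stopf("missing contigs path '%s'", cfg$contigs)
    db <- parseReferenceFasta(cfg$db)
    if (!is.null(cfg$groups)) db <- assignGroups(db, readGroupLabels(cfg$groups))
    db
  })
  db <- st$result
  report$elapsed[["build-db"]] <- st$elapsed
  .log_stage("build-db", "%d reference genes", length(db))

  params <- do.call(searchParams, cfg$search)
  st <- .run_stage("search", {
    contigs <- tryCatch(Biostrings::readDNAStringSet(cfg$contigs),
                        error = function(e) Biostrings::DNAStringSet())
    if (length(contigs) == 0L)
      .warnf("no contigs in '%s'", cfg$contigs)
    names(contigs) <- sub("\\s.*$", "", names(contigs))
    hits <- searchContigs(contigs, db, params)
    writeHitsTSV(hits, file.path(cfg$outDir, "hits.tsv"))
    list(contigs = contigs, hits = hits)
  })
  contigs <- st$result$contigs
  hits <- st$result$hits
  report$elapsed[["search"]] <- st$elapsed
  report$counts$contigs_searched <- length(contigs)
  report$counts$hits <- nrow(hits)
  .log_stage("search", "%d hits on %d contigs", nrow(hits), length(contigs))

  st <- .run_stage("filter", {
    f <- filterHits(hits, params)
    writeHitsTSV(f, file.path(cfg$outDir, "filtered.tsv"))
    f
  })
  filtered <- st$result
  report$elapsed[["filter"]] <- st$elapsed
  report$counts$hits_after_filter <- nrow(filtered)
  cand <- candidateContigs(filtered)
  report$counts$candidate_contigs <- length(cand)
  .log_stage("filter", "%d hits on %d candidate contigs", nrow(filtered),
             length(cand))

  st <- .run_stage("recover", {
    orfs <- do.call(rbind, lapply(cand, function(id)
      findOrfs(as.character(contigs[[id]]), id, cfg$minOrfLen)))
    if (is.null(orfs)) orfs <- .empty_orfs()
    writeGenesGFF3(orfs, file.path(cfg$outDir, "orfs.gff3"),
                   featureType = "open_reading_frame")
    rec <- mapHitsToOrfs(filtered, orfs)
    list(orfs = orfs, rec = rec)
  })
  orfs <- st$result$orfs
  recovered <- st$result$rec$genes
  report$elapsed[["recover"]] <- st$elapsed
  report$counts$orfs <- nrow(orfs)
  report$counts$recovered_genes <- nrow(recovered)
  report$counts$fragment_only_hits <- nrow(st$result$rec$fragment_only)
  .log_stage("recover", "%d ORFs, %d recovered genes", nrow(orfs),
             nrow(recovered))

  st <- .run_stage("curate", {
    cur <- curateCandidates(recovered, db, cfg$minIdentityPct)
    writeGenesGFF3(cur, file.path(cfg$outDir, "recovered.gff3"))
    if (nrow(cur)) {
      nt <- Biostrings::DNAStringSet(setNames(cur$nt, .gene_ids(cur)))
      aa <- Biostrings::AAStringSet(setNames(cur$aa, .gene_ids(cur)))
      Biostrings::writeXStringSet(nt, file.path(cfg$outDir,
                                                "recovered_nt.fasta"),
                                  width = 60L)
      Biostrings::writeXStringSet(aa, file.path(cfg$outDir,
                                                "recovered_aa.fasta"),
                                  width = 60L)
    }
    cur
  })
  curated <- st$result
  report$elapsed[["curate"]] <- st$elapsed
  report$counts$curated_genes <- nrow(curated)
  .log_stage("curate", "%d curated genes", nrow(curated))

  st <- .run_stage("screen", {
    scr <- screenGenes(curated, db, mcoMinHxh = cfg$mcoMinHxh)
    write.table(scr, file.path(cfg$outDir, "screen.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (nrow(scr)) {
      hp <- curated[scr$functional_call == "HIGH_POTENTIAL", , drop = FALSE]
      if (nrow(hp)) {
        aa <- Biostrings::AAStringSet(setNames(hp$aa, .gene_ids(hp)))
        Biostrings::writeXStringSet(aa, file.path(cfg$outDir,
                                                  "high_potential.faa"),
                                    width = 60L)
      }
    }
    scr
  })
  screened <- st$result
  report$elapsed[["screen"]] <- st$elapsed
  report$counts$high_potential_genes <-
    sum(screened$functional_call == "HIGH_POTENTIAL")
  .log_stage("screen", "%d high-potential genes",
             report$counts$high_potential_genes)

  if (isTRUE(cfg$buildTree) && nrow(curated) >= 3L &&
      nrow(curated) <= 40L) {
    st <- .run_stage("tree", {
      seqs <- setNames(curated$aa, .gene_ids(curated))
      tr <- njTree(identityDistances(seqs))
      ape::write.tree(tr, file.path(cfg$outDir, "gene_tree.nwk"))
      rf <- NULL
      if (!is.null(cfg$refTree)) {
        ref <- ape::read.tree(cfg$refTree)
        if (setequal(ref$tip.label, tr$tip.label))
          rf <- robinsonFoulds(tr, ref)
        else .warnf("reference tree leaves differ; congruence skipped")
      }
      rf
    })
    report$elapsed[["tree"]] <- st$elapsed
    if (!is.null(st$result)) report$congruence <- st$result
  }

  stopifnot(report$counts$hits >= report$counts$hits_after_filter,
            report$counts$recovered_genes >= report$counts$curated_genes,
            report$counts$curated_genes >=
              report$counts$high_potential_genes)
  jsonlite::write_json(report, file.path(cfg$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

.gene_ids <- function(genes) {
  sprintf("%s_%d_%d_%s", genes$contig_id, genes$start, genes$end,
          ifelse(genes$strand == "+", "p", "m"))
}
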