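#' Construct a reference database from sequences
#'
#' Builds a [ReferenceDB] from a named [Biostrings::DNAStringSet] (or named
#' character vector), parsing GI number and species from headers that follow
#' the \code{gi_<digits>_<Species_name>} convention. Headers that do not
#' follow the convention keep the full header as record id with an empty GI.
#'
#' @param seqs Named DNAStringSet or named character vector of nucleotide
#'   sequences.
#' @param name Database name.
#' @param defaultGroup Group assigned to every gene (\code{"UNKNOWN"},
#'   \code{"ATPASE"} or \code{"MCO"}).
#' @param sourcePath Recorded source path, if any.
#' @return A [ReferenceDB].
#' @export
referenceDB <- function(seqs, name = "refdb", defaultGroup = "UNKNOWN",
                        sourcePath = "") {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (length(seqs) == 0L) .stopf("empty database")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    .stopf("all reference sequences must be named")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    .stopf("duplicate header in reference database: '%s'", dup[1L])
  chr <- toupper(as.character(seqs))
  bad <- regexpr("[^ACGTN]", chr)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    .stopf("non-IUPAC nucleotide character in record '%s' at position %d",
           ids[i], bad[i])
  }
  seqs <- Biostrings::DNAStringSet(chr)
  names(seqs) <- ids
  m <- regmatches(ids, regexec("^gi_([0-9]+)_(.+)$", ids))
  gi <- vapply(m, function(x) if (length(x) == 3L) x[2L] else "", "")
  species <- vapply(m, function(x) if (length(x) == 3L) x[3L] else "", "")
  defaultGroup <- match.arg(defaultGroup, GENE_GROUPS)
  new("ReferenceDB", seqs = seqs, gi = gi, species = species,
      group = rep(defaultGroup, length(seqs)), name = name,
      sourcePath = sourcePath)
}

#' Parse a reference gene database from FASTA
#'
#' Reads a nucleotide FASTA of curated reference genes (e.g. a local
#' \emph{copA} database) into a [ReferenceDB]. GI and species are parsed from
#' headers of the form \code{gi_<digits>_<Species_name>}; parsing is
#' case-insensitive and sequences are stored uppercase.
#'
#' @param path Path to a FASTA file.
#' @param defaultGroup Group label assigned to every record (see
#'   [assignGroups()] for per-record labels).
#' @return A [ReferenceDB]; the record count equals the number of FASTA
#'   records in the input.
#' @export
parseReferenceFasta <- function(path, defaultGroup = "UNKNOWN") {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) .stopf(
                     "failed to read FASTA '%s': %s", path, conditionMessage(e)))
  if (length(seqs) == 0L) .stopf("empty database")
  # Biostrings keeps full description lines; record id = first token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  referenceDB(seqs, name = basename(path), defaultGroup = defaultGroup,
              sourcePath = path)
}

#' Write a reference database to FASTA
#'
#' Writes sequences wrapped at 60 columns; headers are the record ids, so a
#' parse/write round trip preserves records exactly.
#'
#' @param db A [ReferenceDB].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeReferenceFasta <- function(db, path) {
  Biostrings::writeXStringSet(db@seqs, path, width = 60L)
  invisible(path)
}

#' Assign functional group labels to reference genes
#'
#' @param db A [ReferenceDB].
#' @param labels Named character vector mapping record ids to
#'   \code{"ATPASE"}/\code{"MCO"}/\code{"UNKNOWN"}; unlabeled genes keep their
#'   current group.
#' @return The relabeled [ReferenceDB]; no other field changes.
#' @export
assignGroups <- function(db, labels) {
  stopifnot(is(db, "ReferenceDB"))
  if (length(labels) == 0L) return(db)
  ids <- names(labels)
  if (is.null(ids)) .stopf("labels must be named by record_id")
  missing <- setdiff(ids, names(db@seqs))
  if (length(missing))
    .stopf("unknown record_id in labels: '%s'", missing[1L])
  bad <- setdiff(unique(labels), GENE_GROUPS)
  if (length(bad)) .stopf("unknown group label '%s'", bad[1L])
  g <- db@group
  g[match(ids, names(db@seqs))] <- unname(labels)
  db@group <- g
  validObject(db)
  db
}

#' Read group labels from a two-column TSV
#'
#' Columns: record_id, group. Used by the `build-db` command-line step.
#'
#' @param path TSV path (no header).
#' @return Named character vector suitable for [assignGroups()].
#' @export
readGroupLabels <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("record_id", "group"),
                    colClasses = "character")
  setNames(tab$group, tab$record_id)
}
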