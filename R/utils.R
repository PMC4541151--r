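# shared internal helpers

DNA_BASES4 <- c("A", "C", "G", "T")

# integer encoding A=0 C=1 G=2 T=3 N=4 (anything else caught upstream)
.encode_dna <- function(x) {
  v <- match(strsplit(x, "", fixed = TRUE)[[1]], c(DNA_BASES4, "N")) - 1L
  v
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.translate_nt <- function(nt) {
  # bacterial code (table 11 shares the standard codon table); fuzzy codons -> X
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nt),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "X"))
  unname(aa)
}

# run expr with a temporarily seeded RNG, restoring caller state
.with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

.aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
    "F", "P", "S", "T", "W", "Y", "V")
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
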