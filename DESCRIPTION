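Package: copAminer
Title: Recovery and Motif-Based Screening of Full-Length Copper-Resistance
    Genes from Assembled Metagenomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recovers full-length metal-resistance genes (exemplified by the
    copper-resistance gene copA) from assembled metagenomic contigs. Implements
    a seeded local nucleotide search against a curated reference database with
    Karlin-Altschul E-value statistics and alignment-length/E-value screening
    filters, six-frame ORF-based full-length gene recovery, progressive protein
    multiple alignment with conserved-block trimming, neighbor-joining
    phylogenies with Robinson-Foulds congruence, evolutionary-trace ranking of
    alignment columns, metal-binding-motif screening that separates P-type
    ATPase from multicopper-oxidase candidates, and a synthetic planted-gene
    benchmark with sensitivity/specificity evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    phangorn,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
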