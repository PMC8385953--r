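Package: cksrna
Title: Cross-Kingdom Small RNA Discovery from Plant-Fungal Dual sRNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering candidate cross-kingdom small
    RNAs (ck-sRNAs) in dual sRNA sequencing experiments where a plant root is
    colonized by a fungal endophyte. Covers adapter trimming and read
    collapsing, exact-match alignment of collapsed reads against both
    genomes, structural RNA (tRNA/rRNA) removal, origin classification,
    per-organism reads-per-million normalization, induction selection,
    size and 5-prime nucleotide profiling, ShortStack-style sRNA locus
    calling with DicerCall and known-miRNA matching, seed-weighted
    complementarity target prediction, confirmation of predicted targets
    against differential expression results, and growth-phenotype
    statistics. A synthetic-data generator emulates the statistical
    structure of such experiments and carries a ground-truth ledger, so
    recovery of planted signal is exactly measurable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
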