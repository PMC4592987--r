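Package: refprimer
Title: Reference-Gene Selection and Genome-Wide RT-PCR Primer Catalogs from
    Expression Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects stably expressed qPCR reference genes from expression
    time-course matrices via an expressing/noncircadian/ANOVA-selected (ENCAS)
    filter chain and a prediction-interval ranking score (PIRS), combines
    per-dataset scores by pareto-front and summed-normalized consensus, and
    builds genome-wide ranked RT-PCR primer catalogs from a genome FASTA and
    GFF3 annotation using intron-aware region selection and a nearest-neighbor
    thermodynamic primer search engine. Includes rhythmicity screening with a
    permutation-based Jonckheere-Terpstra-Kendall style test, Ct-table
    replicate filtering and detection summaries, and seeded simulators for
    expression courses, annotated genomes, and Ct tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
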