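Package: teprom
Title: Transposable-Element Content of Gene Promoters and Early Embryonic
    Expression Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline linking the repeat content of gene promoters
    to gene-expression dynamics across pre-implantation development. Provides
    readers for GTF, RepeatMasker, BED, FASTA, MEME and GMT formats normalised
    to a single coordinate convention; strand-aware promoter construction and
    per-gene repeat feature tables (counts split by orientation, coverage,
    distance to TSS); expression filtering, stage fold-changes and clustering;
    an association battery (cluster enrichment, dosage and distance curves,
    rank-bin correlation, multiple regression, gene-set over-representation);
    position-weight-matrix scanning with group ANOVA; genome-wide repeat
    distribution statistics (copy-number lognormal fit, region enrichment,
    strand preference); and a seeded synthetic-data generator with planted
    per-copy, strand-specific, distance-decaying effects for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    methods,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
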