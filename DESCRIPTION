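Package: bsascreen
Title: Bulked-Segregant Screening of Pooled Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bulked-segregant analysis (BSA) of pooled whole-genome
    sequencing from two extreme-phenotype bulks. Computes the per-pool
    SNP/InDel index from allele depths, applies the standard depth and
    low-index filter cascade, screens markers on the difference of the
    two pool indices (delta index) against a simulation-based null
    confidence envelope that models both finite bulk composition and
    binomial read sampling, annotates variants against gene models
    (region class, coding effect, Ts/Tv), anchors candidate markers to
    genes, tests marker-genotype association in validation panels, and
    performs hypergeometric term over-representation analysis. Includes
    a seeded pool-seq simulator so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    vcfR,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
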