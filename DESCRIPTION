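Package: hemiassoc
Title: Case-Control Association Testing on a Hemizygous Genomic Region
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variant-, gene- and region-based case-control association
    testing for variants on a hemizygous genomic segment, where every
    sample contributes a single allele and association reduces to exact
    tests on carrier counts. Implements the retention filters used for
    targeted hemizygous resequencing (caller-specific quality cutoffs,
    population allele-frequency ceiling, dataset-singleton exclusion),
    a coding/splice-site classifier against gene models, variant-centred
    sliding-window burden tests with Bonferroni family-wise control, a
    per-nucleotide normalized-coverage CNV association test, and
    simulation-based power analysis of Fisher's exact test for carrier
    data. Ships a synthetic-cohort generator (multi-sample VCF, GFF3
    gene models, per-base depth tracks, sample manifest) so the whole
    pipeline is testable end to end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
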