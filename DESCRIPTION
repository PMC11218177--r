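Package: mecclone
Title: Clonal Origin and Shared-Variant Analysis for Multifocal Tumor Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clonality analysis for multifocal tumors sequenced as paired
    foci with a matched normal. Classifies somatic variants of a focus pair
    as shared, unique, or excluded (read-level rescue with a loss-of-
    heterozygosity guard and a coverage gate), calls each patient multicentric
    or metastatic from the shared fraction, compares groups with an exact
    Wilcoxon rank-sum enumeration, runs a germline rare-variant filter
    cascade with Cancer Gene Census screening and category enrichment,
    clusters cancer cell fractions with a binomial mixture to call clonal
    structure and key mutations, tallies copy-number and neoantigen
    recurrence across foci, and ships a calibrated synthetic paired-foci
    cohort generator so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
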