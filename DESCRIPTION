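Package: timberID
Title: Forensic Timber Identification from SSR Allele-Frequency and
    Chloroplast Haplotype Databases
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating the DNA databases used in
    forensic timber identification: regional microsatellite (SSR)
    allele-frequency databases with minimum-allele-frequency floors,
    per-locus forensic parameters (heterozygosity, PIC, matching
    probability, power of discrimination) with Hardy-Weinberg and
    linkage-disequilibrium exact tests, Weir-Cockerham coancestry and
    inbreeding estimation with locus bootstraps, genotype and multilocus
    profile frequencies under the subpopulation-cum-inbreeding model,
    conservativeness evaluation and coancestry calibration, leave-one-out
    Bayesian self-assignment, Nei's DA / UPGMA population trees, and a
    chloroplast intergenic-spacer haplotype database with regional origin
    inference. A hierarchical genotype and haplotype simulator provides
    fully reproducible synthetic data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
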