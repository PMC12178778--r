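Package: irdprior
Title: Prioritization of Gene Supplementation Therapy Candidates for
    Inherited Retinal Dystrophies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An offline, reproducible pipeline for ranking inherited
    retinal dystrophy (IRD) genes as adeno-associated virus (AAV) gene
    supplementation candidates. Computes per-gene autosomal-recessive
    carrier frequency, genetic prevalence and expected affected
    individuals from stratified pathogenic allele-frequency tables;
    pools per-gene diagnostic yields across sequencing cohorts by
    weighted averaging with inclusion-criteria filtering and
    sensitivity analyses; summarizes cell-type-resolved expression
    (dot-plot statistics, highly-variable-gene selection, tau
    specificity) from labeled single-cell count matrices; and applies
    the candidate filter combining AAV cargo-size compatibility,
    disease burden above a reference gene, and enzyme-coding class.
    Includes seeded synthetic-data generators with planted ground
    truth so the whole pipeline is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
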