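Package: trioburden
Title: Rare-Variant Burden, Transmission and Meta-Analysis for Trio Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for identifying dominant disease genes from
    targeted sequencing of proband trios and singletons: de novo mutation
    burden against per-gene mutability expectation, case-control burden of
    very rare variants with coverage harmonization, joint-local false
    discovery rate (JL-FDR) meta-analysis via a two-component bivariate
    normal mixture fitted by EM, transmission disequilibrium testing,
    risk-gene-count estimation by Monte-Carlo maximum likelihood,
    attributable fractions, and phenotype-subgroup and protein-region
    enrichment. Includes a trio-cohort simulator with known ground truth so
    every stage is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
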