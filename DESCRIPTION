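Package: neoescape
Title: Cohort Analysis of Somatic B2M/HLA Mutations and Neoantigen
    Presentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying tumor immune escape through somatic
    mutations of the MHC class I machinery (B2M and the HLA-A/B/C heavy
    chains). Implements patient harmonic-mean best-rank (PHBR) scoring of
    neoantigen presentation from per-allele binding percentile ranks,
    mutant-allele binding-bias statistics, variant-allele-fraction
    percentile timing of escape mutations with copy-number exclusion,
    microsatellite-instability stratification, expressed nonsynonymous
    mutation burden, cytolytic immune activity scores, residue-level
    structural annotation (core/surface/interface/ambiguous) of B2M/HLA
    proteins with hotspot and domain-enrichment analysis, and a seeded
    synthetic-cohort generator that emulates the statistical structure of
    these analyses so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
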