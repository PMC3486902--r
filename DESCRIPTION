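Package: icecohort
Title: Inter-Chromosomal Effect Analysis for Oocyte and Preimplantation
    Embryo Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the inter-chromosomal effect (ICE) in
    oocytes and preimplantation embryos of chromosome-rearrangement
    carriers. Parses an ISCN subset of carrier karyotypes (Robertsonian and
    reciprocal translocations, inversions), tallies whole-chromosome
    aneuploidies from per-sample copy-state calls after excluding the
    rearranged chromosomes, rescales patient-matched control groups to the
    matched patient's chromosome count, and tests for excess malsegregation
    with Yates-corrected chi-squared statistics and relative risks,
    stratified by rearrangement class, biopsy stage, and carrier sex. A
    seedable synthetic-cohort generator and a whole-chromosome microarray-CGH
    ratio simulator with a median-threshold caller make every stage of the
    pipeline runnable and testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
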