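Package: srsignal
Title: Disproportionality Signal Detection and Network Pharmacology for
    Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection in spontaneous
    reporting system (SRS) extracts such as FAERS, JADER and CVAR:
    ingestion and deduplication of the three database dialects, drug-name
    normalization, report-level 2x2 contingency tables and four
    disproportionality statistics (reporting odds ratio, proportional
    reporting ratio with Pearson chi-square, Bayesian information
    component, and the gamma-Poisson shrinker EBGM) with a joint signal
    criterion, subgroup and co-medication analyses, Weibull time-to-onset
    profiling with failure-type classification, and a network-pharmacology
    stage (target-set intersection, MCODE clustering of protein-protein
    interaction networks, hypergeometric enrichment). A synthetic-report
    generator with known ground truth supports end-to-end testing without
    access to the raw databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    fitdistrplus,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
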