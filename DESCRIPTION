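Package: hscna
Title: Copy Number, LOH and Breed Association Analysis for Canine
    Histiocytic Sarcoma Cohorts
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for molecular-cytogenetic analysis of two-breed
    canine histiocytic sarcoma cohorts assayed on a 1-Mb BAC array.
    Calls per-case copy number aberrations (CNAs) from log2
    tumor:reference ratios with a moving-median smoother and ratio
    thresholds, aggregates calls into cohort penetrance tracks with
    recurrent and highly recurrent region classification, scores
    microsatellite loss of heterozygosity from paired tumor/blood peak
    areas via allelic-imbalance ratios, tests per-region breed
    association with Fisher's exact tests under permutation-based
    family-wise error control, and examines population substructure by
    principal component analysis of the case-by-interval aberration
    matrix. Ships a synthetic-cohort generator that plants recurrent
    aberrations at declared frequencies so the whole pipeline is
    testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
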