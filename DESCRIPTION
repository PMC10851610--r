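Package: ctabr
Title: Cancer Testis Antigen Burden Scoring and Immunotherapy Outcome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the cancer testis antigen burden (CTAB), a rank-sum
    biomarker of aggregate cancer testis antigen (CTA) expression in solid
    tumors. Expression of a 17-gene CTA panel is converted to percentile
    ranks (0-100) against a fixed reference population and summed into an
    integer score in [0, 1700], dichotomized at 170 into CTAB high and low.
    Includes Spearman co-expression network construction and grouping of the
    panel, stratification of CTAB by PD-L1 tumor proportion score and tumor
    mutational burden, Kaplan-Meier overall-survival and objective-response
    analyses for immune-checkpoint-inhibitor-treated cohorts, and a
    calibrated synthetic-cohort generator (reference population, pan-cancer
    discovery cohort, and a two-arm treated NSCLC cohort) so the whole
    pipeline is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
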