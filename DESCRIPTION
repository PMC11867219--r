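Package: fhburden
Title: Family-History-Weighted Burden Association Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-based rare-variant burden association testing that
    incorporates first-degree family history through a weighted composite
    phenotype. Implements reversed logistic regression models in which
    carrier status is regressed on disease status, family history and sex
    (the null model and Models 1-3, including the constrained composite
    Case + k*FH model), adjacent-categories per-allele models for common
    variants, a kinship-weighted pedigree score test with its rare-disease
    reduction, closed-form effective sample sizes for the competing
    analysis strategies, and a Monte-Carlo engine for power and type-I
    error under biobank-like cohort compositions. Includes variant
    filtering utilities (allele-frequency thresholds and the positional
    nonsense-mediated-decay escape rule) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
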