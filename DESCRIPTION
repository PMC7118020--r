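Package: vuslr
Title: Clinical-History Likelihood Ratios for BRCA1/BRCA2 Variant Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multifactorial evidence pipeline for classifying BRCA1/BRCA2
    variants of uncertain significance from personal and family cancer
    history. Fits per-gene, per-ancestry logistic regressions of
    pathogenic-carrier status on 29 clinical-history indicators, converts
    predicted carrier probabilities into per-individual and per-variant
    likelihood ratios of pathogenicity, estimates the proportion of
    pathogenic variants within bioinformatically defined classes via an
    admixture likelihood with profile-likelihood confidence intervals, and
    combines likelihood ratios with prior probabilities into posterior
    classifications. Includes a synthetic-cohort generator with the
    statistical structure the analysis assumes, so the full pipeline is
    testable without proprietary clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
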