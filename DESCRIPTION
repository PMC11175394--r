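Package: hivcanmatch
Title: Record Linkage and Cross-Province Cancer-Diagnosis Flows for HIV Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for supervised record linkage between HIV laboratory
    records and cancer pathology records, cohort construction under
    registry-style eligibility filters, and quantification of
    cross-province cancer-diagnosis flows among people living with HIV.
    Includes a synthetic record generator with ground-truth entity
    identities and a configurable home-province to diagnosis-province
    mobility matrix, name standardization and phonetic blocking,
    Jaro-Winkler comparison vectors classified with a linear
    maximum-margin model, union-find deduplication, origin-destination
    matrices with column percentages, demographics tables, chi-square
    tests, logistic regression odds ratios, and GeoJSON flow export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
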