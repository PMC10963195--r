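Package: thyrosig
Title: Thyroid Homeostasis Signatures and Outcome Modelling in Stress Cardiomyopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes calculated parameters of thyroid homeostasis (SPINA-GT,
    SPINA-GD, Jostel's TSH index, TTSI, TFQI) from admission thyroid panels,
    classifies thyroid allostasis endotypes, discovers TSH-by-FT4 clusters with
    a deterministic k-medoids (PAM) implementation selected by average
    silhouette width, derives survival cutoffs from phi statistics and
    Youden's J, and runs a Kaplan-Meier / Cox proportional-hazards survival
    stack with stepwise minimal-model selection and frailty adjustment.
    Includes a registry-matched synthetic cohort generator so the whole
    pipeline is exercisable and testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
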