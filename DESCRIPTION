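Package: msnkit
Title: Morphometric Similarity Networks from Parcellated Cortical Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-subject morphometric similarity networks (MSNs) from
    region-by-feature cortical morphometry tables, compares nested feature
    models (10-, 8- and 7-feature) under proportional density thresholding,
    quantifies edge-level similarity (Pearson, Mantel, binary edge
    replication), assesses test-retest and subject-versus-group reliability,
    and relates nodal network metrics to cognition via partial least squares
    regression with Q-squared cross-validated component selection and BCa
    bootstrap predictor weights. Includes a latent-factor synthetic-cohort
    generator so every stage is testable without restricted neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
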