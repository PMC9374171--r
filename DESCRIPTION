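Package: somnotype
Title: Unsupervised Subtyping of Sleep-Disturbance Survey Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for data-driven subtyping of
    sleep-disturbance survey respondents. Generates synthetic item-level
    survey cohorts with a configurable latent cluster structure, scores
    the standard instruments (Pittsburgh Sleep Quality Index, Berlin
    questionnaire, Nutrition Quotient, Gastrointestinal Symptom Rating
    Scale, Bristol stool scale), applies a staged cleaning and filtering
    chain, extracts low-dimensional features by principal component
    analysis and by a symmetric deep autoencoder with cross-validated
    bottleneck selection, clusters the features with k-means under
    internal validity indices (Calinski-Harabasz, silhouette, elbow on
    within-cluster sum of squares), and validates clusters externally
    with one-way ANOVA, Tukey-Kramer post-hoc comparisons, chi-squared
    tests and odds ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
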