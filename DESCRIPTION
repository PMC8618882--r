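Package: chemsens
Title: Oral Chemesthesis Sensitivity Phenotyping from Intensity Ratings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segments consumers into oral chemesthesis sensitivity groups
    from 0-10 line-scale intensity ratings of astringency, pungency and
    cooling sample series. Implements agglomerative hierarchical clustering
    with squared Euclidean distances and Ward's method, intensity-ordered
    cluster labelling, the composite Chemesthesis Sensitivity Score (CSS)
    with its seven-value lattice and hypo/semi/hypersensitive categories,
    one-way MANOVA with all four multivariate test statistics,
    per-concentration Tukey HSD with compact letter displays, and
    baseline-category multinomial logistic regression with stepwise
    predictor selection for cross-modality and chemesthesis-taste
    interactions. Includes a latent-trait synthetic cohort generator so the
    full pipeline is testable without access to the original panel data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr
Config/testthat/edition: 3
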