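Package: fslink
Title: Data-Adaptive Fellegi-Sunter Probabilistic Record Linkage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Probabilistic record linkage and deduplication with the
    Fellegi-Sunter latent class model. Fits match prevalence and per-field
    agreement probabilities (m- and u-probabilities) by the EM algorithm
    under two treatments of missing field comparisons: missing-as-disagreement
    (zero filling) and a missing-at-random full-information likelihood that
    skips unobserved comparisons. Includes exact-agreement blocking over
    multiple schemes, data-driven selection of matching fields, log
    likelihood-ratio match scoring with a prevalence-quantile threshold,
    gold-standard evaluation (sensitivity, specificity, PPV, NPV, F1) with
    bootstrap confidence intervals, and a synthetic-data generator with
    pluggable missingness mechanisms (MCAR, class-dependent MAR,
    value-dependent MNAR) for validation without access to protected records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
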