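Package: grazemeta
Title: Meta-Analysis of Livestock Grazing-Exclusion Experiments in
    Grasslands
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for synthesizing paired grazed-versus-exclosure
    comparisons from grassland field experiments. Computes log response
    ratio effect sizes with their sampling variances, pools them by
    inverse-variance weighting under fixed- and random-effects
    (DerSimonian-Laird) models, quantifies heterogeneity (Cochran's Q,
    I-squared, tau-squared), runs subgroup contrasts and weighted
    meta-regression on exclusion duration, and provides leave-one-out and
    targeted-exclusion influence diagnostics. Includes a synthetic
    comparison-table generator with known ground truth for validation, a
    dispersion-imputation ladder for incompletely reported studies, and
    plot-ready forest- and bubble-plot exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
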