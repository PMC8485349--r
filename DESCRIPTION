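Package: chemoselect
Title: Chemometric Biomarker Selection for Label-Free Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for biomarker discovery from label-free
    (SWATH-type) protein abundance matrices: univariate fold-change plus
    t-test screening, principal component analysis after autoscaling,
    batch-trained Kohonen self-organizing maps on hexagonal toroidal grids
    with PCA-on-weights interpretation, and two-class PLS-DA with
    VIP-driven backward elimination validated by repeated leave-more-out
    cross-validation. Includes a synthetic abundance-data generator with
    planted ground truth (fold changes, gender effects, phenotype
    correlations) so that every stage of the analysis is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
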