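Package: coldrange
Title: Metabolic Constraints on Endotherm Cold Range Boundaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether the cold (poleward) range boundaries of
    birds and mammals are set by limits on how far metabolism can be elevated
    above basal rates. Implements Scholander-Irving heat-balance arithmetic
    (thermal conductance, boundary metabolic rate, metabolic expansibility,
    thermal-limit inversion), extraction of per-longitude range-boundary cells
    from presence grids and summaries of boundary temperatures, distribution
    shape inference for metabolic expansibility (kernel-density peaks with
    subpeak averaging, D'Agostino skewness and Bonett-Seier kurtosis tests,
    Hartigan's dip test with Monte Carlo p-values, randomization null models),
    trait regressions with exhaustive AICc model selection and model averaging,
    and thermal-isocline projection of current and future cold range boundaries
    (habitability masking, connected-component clump filtering, boundary
    latitude and poleward shift). A seeded synthetic-world generator provides
    climate grids, physiologies, traits and range masks with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    tools,
    mgcv,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    quadprog
Config/testthat/edition: 3
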