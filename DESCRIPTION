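Package: eggtexture
Title: Areal Surface Texture and Phylogenetic Comparative Analysis of
    Eggshell Height Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies areal surface texture parameters (Sa, Sq, Ssk, Sku)
    from three-dimensional height maps of eggshell fragments, with
    polynomial form correction, missing-pixel handling and coverage-based
    quality control; aggregates scan-level measurements to specimen and
    species level with repeatability estimation and Cook's-distance
    influence filtering; and fits the phylogenetic comparative stack used
    in macroecological studies of eggshell texture: Pagel's lambda signal
    tests, phylogenetic generalized least squares, a collinearity/VIF
    predictor screen, and a Gaussian phylogenetic mixed model (animal
    model) estimated by Gibbs sampling with pMCMC, highest posterior
    density intervals and batched posterior prediction grids. Includes a
    synthetic-data module that generates height maps, Yule phylogenies and
    trait datasets with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    lme4,
    stats,
    utils
Suggests:
    phytools,
    nlme,
    car,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
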