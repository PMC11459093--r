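Package: chronophylo
Title: Phylogenetic Diversity, Community Structure and Aboveground Biomass
    Along Vegetation-Recovery Chronosequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for linking plant evolutionary diversity to aboveground
    biomass (AGB) along successional chronosequences. Computes Faith's
    phylogenetic diversity, phylogenetic species variability, richness and
    evenness (PSV, PSR, PSE), mean pairwise and nearest-taxon distances, and
    standardized phylogenetic structure (NRI, NTI) against richness-preserving
    randomization nulls drawn from the whole phylogeny pool. Estimates
    plot-level AGB from harvest boxes and species-specific allometric
    equations, fits polynomial chronosequence trends, one-way ANOVA with
    Duncan multiple-range letters, linear mixed models with marginal and
    conditional R-squared, variance partitioning between predictor sets, and
    partial least squares path models with goodness of fit. Includes a
    synthetic chronosequence generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    car,
    lme4,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
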