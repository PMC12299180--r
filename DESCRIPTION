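Package: phylotopo
Title: Phylogenetic Community Structure Across Spatial Grains and Life Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for analysing the phylogenetic structure of mapped forest
    plots in relation to microtopography and neighbourhood competition.
    Tiles a stem-mapped census into nested quadrat grids (2.5, 5 and 10 m),
    computes species richness, Faith's phylogenetic diversity, the net
    relatedness index (NRI) and nearest taxon index (NTI) under a
    tip-label randomisation null, derives terrain covariates (slope,
    aspect, TPI, TRI, roughness, D8 flow accumulation) from an elevation
    raster, computes Hegyi's distance-weighted competition index per stem,
    and fits linear mixed-effects models linking the diversity responses
    to the standardised covariates per scale and DBH-defined life stage.
    Includes a synthetic-forest generator (Yule phylogenies, smooth DEMs,
    stem maps with controllable environmental filtering or phylogenetic
    repulsion) so the whole chain is testable end to end with known
    assembly structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    lme4,
    stats,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
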