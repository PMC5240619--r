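Package: divcarbon
Title: Multi-Scale Analysis of Tropical Forest Tree Diversity and Aboveground Carbon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the relationship between tree diversity and
    aboveground live-carbon stocks in tropical forest inventory plots at
    multiple spatial scales. Converts stem-level inventory tables into
    per-unit-area carbon estimates via height-diameter and biomass allometry,
    computes alpha-diversity metrics (corrected taxon richness,
    individual-based rarefaction, Fisher's alpha), models the distance decay
    of Sorensen similarity with bootstrap envelopes, performs stand-scale
    inference (Kendall correlations, power analysis, AICc all-subsets model
    averaging, simultaneous autoregressive error models), within-plot
    subplot-scale regressions and random-coefficient mixed models, and
    selection-effect / niche-complementarity diagnostics based on
    community-weighted traits and species-pool null models. Includes a
    synthetic inventory generator with known ground truth so that every
    stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    pracma,
    lme4,
    multcomp,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
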