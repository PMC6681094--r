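Package: floraluv
Title: Phylogenetic Comparative Analysis of Floral Ultraviolet Pigmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking floral ultraviolet (UV) pigmentation to
    geography and bioclimate across a phylogeny. Implements trait
    classification from petal UV proportion, phylogenetic signal estimation
    (Blomberg's K with a contrast-variance randomization test, Pagel's lambda
    by maximum likelihood with a likelihood-ratio test), phylogenetic
    generalized estimating equations for a binary pattern state with a
    unit-branch-length working correlation, phylogenetic least-squares
    regression under Brownian-motion and Ornstein-Uhlenbeck covariance with
    AIC and likelihood-ratio model comparison, independent-contrast
    regression through the origin, phylogenetic standardization of
    predictors, simulation-based phylogenetic ANOVA, aggregation of any
    analysis over a posterior sample of trees, and a synthetic-data
    generator reproducing the joint structure of a species-level floral UV
    study for testing every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    MASS,
    phangorn,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    picante,
    nlme
Config/testthat/edition: 3
RoxygenNote: 7.3.3
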