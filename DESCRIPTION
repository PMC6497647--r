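Package: infonetscore
Title: Informational Network Analysis of Multivoxel fMRI Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives per-subject scalar "neural scores" of concept knowledge
    from item-level fMRI activity patterns. Implements the informational
    network analysis (univariate voxel selection, whole-brain searchlight
    dissimilarity matrices, multiscale-bootstrap hierarchical clustering with
    approximately unbiased cluster p-values, multidimensional scaling, and a
    radial-kernel support vector classifier of expert category structure)
    together with two comparator scores (whole-brain univariate contrast and
    searchlight representational similarity analysis), a linear mixed-effects
    validation layer, group localization maps, and a seeded synthetic-cohort
    generator with planted category structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ape
Config/testthat/edition: 3
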