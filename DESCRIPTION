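Package: wmiem
Title: Inverted Encoding Models and Tuning-Modulation Simulations for
    Working-Memory fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how orientation representations in early
    visual cortex change across working-memory states. Provides a
    counterbalanced trial-design generator for remember-both /
    remember-single delayed-discrimination experiments, a forward
    simulator of voxel responses built from idealized orientation
    tuning channels with parametric gain, width and shift modulations,
    an inverted encoding model (channel weight estimation, inversion,
    re-centered reconstructions and representational fidelity),
    three-class penalized logistic-regression decoding with an
    evidence-difference statistic, permutation-based group inference
    (signed-rank second level and repeated-measures ANOVA), and
    grid-plus-simplex fitting of the simulator's modulation parameters
    to target reconstructions with nested F-test model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    withr
Config/testthat/edition: 3
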