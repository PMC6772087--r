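Package: tarsalSSM
Title: Statistical Shape Modelling of Subtalar Joint Bones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three-dimensional statistical shape modelling (SSM) of tarsal
    bones such as the talus and calcaneus. Provides triangulated-surface
    I/O (PLY, STL, OBJ), centroid-size normalisation and sagittal
    mirroring, unbiased groupwise similarity registration of bone point
    clouds to an evolving Gaussian-mixture mean, dense one-to-one surface
    correspondence using point coordinates and normals via linear
    assignment, PCA point-distribution models with mode retention by
    explained variance, and mode-wise group comparison (Lilliefors-style
    normality screening, one-way ANOVA with Bonferroni post-hoc pairwise
    tests, and age- and gender-adjusted ANCOVA). A synthetic bone-cohort
    generator with planted orthogonal deformation modes, group effects and
    known ground truth makes every stage testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
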