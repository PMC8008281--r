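Package: fetalmorph
Title: Fetal Brain Morphometry and Socioeconomic Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the association between parental
    socioeconomic status and fetal brain development from labelled
    segmentation volumes and triangulated cortical surfaces.  Provides
    Hollingshead-style two-factor socioeconomic scoring, label-based
    volumetry in world (mm) coordinates, convex-hull-referenced cortical
    folding metrics (local gyrification index and sulcal depth) on
    gray-white junction meshes, a linear mixed-effects and nonparametric
    statistical battery with Benjamini-Hochberg control, and a seeded
    synthetic-data generator (cohorts, labelled volumes, folded surfaces)
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    lme4,
    nortest,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
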