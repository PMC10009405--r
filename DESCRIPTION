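Package: isacog
Title: Self-Awareness of Cognitive Deficits: Scoring, Classification and
    Voxel-Wise Metabolic Correlates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying impaired self-awareness of cognitive
    deficits (ISAcog) in Parkinson's disease and related cohorts.
    Implements control-referenced z-scoring of a ten-test
    neuropsychological battery, Movement Disorder Society Level II
    classification of mild cognitive impairment with domain subtyping,
    Cognitive Failures Questionnaire scoring and the objective-subjective
    discrepancy (ISAcog) statistic, nonparametric group statistics with
    Bonferroni-adjusted post-hoc tests and covariate-adjusted partial
    correlations, and voxel-wise regression of brain volumes on ISAcog
    with cluster-forming thresholding and cluster-level family-wise-error
    inference by Freedman-Lane permutation. A synthetic cohort generator
    produces behavioral tables and smoothed volumetric images with known
    planted effects so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
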