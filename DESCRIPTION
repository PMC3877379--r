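Package: patreg
Title: Multimodal High-Dimensional Pattern Regression for Imaging
    Biomarkers of Cognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts continuous cognitive composite scores from structural
    (gray- and white-matter density) and functional (PET-like cerebral blood
    flow) brain volumes. Regional features are generated by watershed
    clustering of voxelwise correlation maps, modelled with relevance vector
    regression (sparse Bayesian kernel regression), selected by backward and
    forward recursive feature elimination against left-out validation error,
    and summarised as voxelwise contribution maps via the discriminative
    direction of the fitted regressor. Includes leave-k-out cross-validation
    orchestration, permutation-based model comparison, a mass-univariate GLM
    baseline, and a synthetic cohort generator with planted brain-behaviour
    signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    kernlab
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
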