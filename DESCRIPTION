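Package: neuropet
Title: Volumetric CNN and Transfer-Learning Classification of Synthetic
    FDG-PET Brain Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a comparative analysis of neurodegenerative-disorder
    classification from volumetric brain scans. Generates synthetic
    template-space FDG-PET-like cohorts with class-specific regional
    hypometabolism (Alzheimer's disease, mild cognitive impairment, dementia
    with Lewy bodies, cognitively normal, plus external frontotemporal
    cases), preprocesses volumes (slice trimming, per-scan feature-wise
    standardisation, [0,1] rescaling, 3D-to-2D mosaic encoding), trains a
    compact 3D convolutional network with kernel-depth variants and
    frozen-backbone transfer-learning heads under an Adadelta protocol with
    early stopping, evaluates with stratified splits, repeated k-fold
    cross-validation, normalised mutual information, one-vs-rest ROC/AUC and
    2D feature embeddings, computes occlusion-sensitivity cross-entropy maps
    with per-class averaging and mosaic projection, and probes
    out-of-distribution robustness on external dementia types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    png,
    pROC,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
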