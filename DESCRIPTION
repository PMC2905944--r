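Package: icaseed
Title: Hybrid ICA-Seed-Based Functional Connectivity Mapping for fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing brain functional connectivity from 4D
    fMRI-like data with hybrid methods that use spatial independent
    component analysis (ICA) to choose seeds for seed-based general
    linear model (GLM) mapping. Implements PCA whitening with
    information-criterion model-order selection, fixed-point spatial
    ICA with symmetric decorrelation, temporal-concatenation group ICA
    with back-reconstruction, five seed constructions (single-voxel,
    few-voxel, many-voxel, and dual regression against one or all
    component maps), voxelwise GLM with Gaussianised z maps and
    familywise or false-discovery-rate thresholding, evaluation
    statistics (Fisher-z spatial correlation, threshold-adjusted
    overlap, partial area under the ROC curve, sensitivity and
    specificity), and a seeded synthetic BOLD phantom generator with
    full ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
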