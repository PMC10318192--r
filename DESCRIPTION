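Package: imgtx
Title: Sex-Stratified Imaging-Transcriptomics Analysis of Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline linking voxelwise resting-state
    functional-activity metrics (amplitude of low-frequency fluctuation,
    regional homogeneity, degree centrality) to regional gene-expression
    profiles. Provides multi-site empirical-Bayes (ComBat) harmonization,
    sex-stratified voxelwise group comparison with FDR and cluster-extent
    control, microarray probe filtering and region-level aggregation,
    partial least squares transcriptome-neuroimaging association with
    permutation and bootstrap inference, and cross-validated prediction of
    clinical scores. A synthetic-data generator with known ground truth
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    sva,
    mixOmics,
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
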