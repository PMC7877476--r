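Package: decodelight
Title: Searchlight Decoding of fMRI Beta Series with Expertise Correlation Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end multivoxel pattern analysis (MVPA) workflow linking
    whole-brain searchlight decoding of functional MRI to individual behavioral
    expertise. Provides trial-wise beta-series estimation by ordinary
    least-squares GLM with canonical double-gamma HRF regressors, discrete-cosine
    drift and motion nuisance terms; sphere-based searchlight feature extraction;
    leave-one-run-out linear support-vector-machine decoding with nested
    cross-validated cost selection, train-only z-scaling with outlier clipping,
    and inverse-frequency class weighting for imbalanced label sets; group-level
    random-effects inference by max-statistic permutation (voxel-wise familywise
    error control for above-chance accuracy, cluster-extent control for
    accuracy-behavior correlation) and conjunction mapping. A synthetic
    multi-subject cohort generator with known region-level ground truth supports
    parameter-recovery and error-control testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools,
    parallel
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
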