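Package: soundmvpa
Title: Multivoxel Pattern Decoding of Natural Sounds from Visual Cortex fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete, testable pipeline for decoding natural sound identity from
    blocked fMRI activity patterns in retinotopic visual cortex and control regions.
    Includes a synthetic multi-subject cohort simulator (block design, HRF convolution,
    AR(1) noise, eccentricity-graded condition patterns), single-block GLM beta
    estimation with cosine high-pass filtering, train-set-normalised one-versus-one
    linear SVM decoding under leave-one-run-out cross-validation, permutation and
    bootstrap inference with max-statistic and FDR multiple-comparison correction,
    rank-based and repeated-measures group statistics with linear eccentricity
    contrasts, and cubic-searchlight mapping with cluster-extent and sign-permutation
    (pseudo-t) group inference.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
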