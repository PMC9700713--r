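Package: hgfmmn
Title: Model-Based Single-Trial EEG Analysis of Auditory Mismatch Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a three-level binary hierarchical Gaussian filter (HGF) as a
    Bayes-optimal learner to auditory oddball tone sequences and regresses the
    resulting precision-weighted prediction-error and uncertainty trajectories
    against single-trial EEG amplitudes over a smoothed two-dimensional scalp
    by peristimulus-time volume. Provides random-effects group inference with
    permutation-based family-wise error control at peak and cluster level,
    ANCOVA against clinical symptom scores, classical mismatch-negativity and
    quantile-split ERP summaries, and a synthetic-data module that simulates
    oddball cohorts with trajectory-locked EEG effects so the full pipeline is
    testable without access to patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    signal,
    interp,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
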