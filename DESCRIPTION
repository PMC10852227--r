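Package: subtrf
Title: Subcortical Temporal Response Functions from Continuous-Speech EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of subcortical (brainstem) temporal response functions
    from single-channel EEG recorded during continuous speech listening.
    Provides auditory-periphery predictor models of increasing complexity
    (rectified speech, gammatone filterbank, inner-hair-cell transduction,
    adaptation loops), unregularized frequency-domain TRF deconvolution with
    inverse-variance trial weighting and polarity-pair averaging, wave V peak
    detection with SNR scoring against circular-shift null models,
    leave-one-out cross-validated prediction correlations over increasing data
    lengths, nonparametric group statistics, and a synthetic-session generator
    so that every stage of the analysis can be verified without access to the
    original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    Rcpp,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
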