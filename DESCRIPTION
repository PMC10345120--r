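Package: flygate
Title: Threat-Gated Visual Aversion Analytics for Walking Drosophila
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for closed-loop walking-arena experiments in
    which a mechanical threat (air puffs) gates aversion from a visual object,
    together with the matching calcium-imaging analytics. Implements the
    closed-loop arena geometry (tracker calibration, 192-to-10 Hz
    downsampling, gain-scaled object-angle updates, balanced stimulus
    schedules), ethogram post-processing with confidence thresholding and
    trial/fly exclusion filters, avoidance and bar-fixation indices,
    fluorescence trace analytics (percent dF/F0, z-scoring, puff-responder
    classification, peak responses), Morlet continuous wavelet spectra with
    frequency-band power and delta-power statistics restricted to
    puff-responsive cells, a normality-gated statistics harness with
    count-dependent multiplicity correction, a from-scratch convolutional
    frame classifier, and seed-controlled synthetic cohort generators that
    emulate the assumed data structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
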