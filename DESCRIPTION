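Package: semgsel
Title: Feature Extraction and Evaluation for Surface EMG Gesture Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surface electromyography (sEMG) gesture-classification
    studies: extraction of 37 time- and frequency-domain features per channel
    (MAV, WL, ZC, SSC, WAMP, spectral moments and others), six filter and
    wrapper feature-evaluation methods (mutual information, univariate F test,
    recursive feature elimination, extra-trees importance, minimum-redundancy
    maximum-relevance, backward elimination), a k-nearest-neighbour evaluation
    protocol with n-best sweeps, channel-membership reporting and greedy
    subset refinement, plus a synthetic multi-channel sEMG generator with
    known informative-channel structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    class,
    glmnet,
    ranger,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
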