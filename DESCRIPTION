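Package: lexidecode
Title: Transfer Decoding and Decoding-Informed Connectivity for Phonological Neighborhood MEG/EEG Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for isolating phonological wordform representations from
    source-space MEG/EEG recordings of lexical-decision experiments built
    around phonological neighborhoods. Implements the blocked hub/neighbor
    experimental design, a multi-subject synthetic generator of ROI-subdivision
    epoch tensors with controllable segmental, lexical and coupling structure,
    trial preprocessing (baseline correction, per-ROI vector normalization,
    random pseudo-trial bin averaging), per-timepoint pairwise transfer
    decoding with linear support vector machines, group-level cluster-based
    sign-flip permutation inference with Bonferroni control across regions,
    and decoding-informed time-varying Granger causality via an adaptive
    Kalman-filter MVAR with surrogate calibration, binomial comparison to a
    control region pair and Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
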