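Package: dpifuse
Title: Dynamic Probability Integration for Human-Computer Fusion in RSVP Target Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Late fusion of a human-vision detector (an EEG decoder for rapid
    serial visual presentation tasks) and a computer-vision detector using
    Dempster-Shafer evidence theory. Basic probability assignments are built
    from smoothed threshold-dependent detection-performance curves (TPR and
    TNR versus decision threshold) fitted on validation data, combined with
    Dempster's rule, and decided through a pignistic transform. Includes the
    STHCP EEG decoder (common spatial patterns, per-channel temporal PCA and
    a shrinkage linear discriminant), naive Bayesian and dynamic belief
    fusion baselines, a fourfold 2:1:1 cross-validation evaluation protocol,
    and a synthetic RSVP generator producing EEG epochs with controllable
    event-related potential structure plus paired detector score streams.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    graphics
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
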