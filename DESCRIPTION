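Package: somnorate
Title: Firing-Rate Dynamics Across Sleep States with Regression-to-the-Mean
    Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of how neuronal firing-rate distributions change within
    and across sleep/wake states. Provides interval algebra over hypnograms,
    epoch-duration filtering and state-sequence extraction, quintile-resolved
    firing-rate dynamics and coefficient-of-variation tracking, the
    shuffle-corrected deflection index that removes regression-to-the-mean
    bias from change-index estimates, detectors for OFF, microarousal and LOW
    substates inside NREM sleep, and a synthetic-session generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
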