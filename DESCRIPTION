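Package: salientime
Title: Salient-Event Accumulation and Predictive Modelling of Subjective
    Time from Trial-Wise fMRI Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links trial-wise parcellated BOLD dynamics to subjective
    duration reports through three complementary routes: accumulation of
    salient network change events detected against an exponentially
    decaying stochastic criterion with reset, followed by support-vector
    regression of video duration and mixed-model tests of scene effects
    on normalized duration bias; a two-layer masked LSTM regressor over
    variable-length trial series; and trial-wise functional-connectivity
    elastic-net prediction with a random-window control for the
    trial-length confound. Includes a seeded synthetic cohort generator
    with planted network-event/report coupling that emulates a
    naturalistic video-watching experiment, plus readers and writers for
    an on-disk cohort layout and an optional volumetric (NIfTI)
    region-extraction path.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    glmnet,
    lme4,
    jsonlite,
    withr,
    RNifti,
    stats,
    utils,
    graphics
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
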