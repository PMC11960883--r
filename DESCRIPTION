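Package: momentqc
Title: Clinical Acceptability Labeling of Predicted Joint Moments in Gait Analysis
Version: 0.1.0
Authors@R:
    person("momentqc", "developers", email = "momentqc@example.org", role = c("aut", "cre"))
Description: A three-step pipeline for judging the clinical acceptability of
    model-predicted lower-extremity joint moments during the stance phase of
    gait, developed around cerebral palsy cohorts. Prediction error between
    measured and predicted hip, knee and ankle moments is summarised as a
    normalised root-mean-square error, thresholded against per-trace lower
    and upper kinetic limits derived from the standardised peak moment, and
    reported as a Green/Yellow/Red traffic-light label. Sagittal kinematic
    features (MAX, ROM, MEAN) and the Gait Profile Score are profiled by
    label, label feasibility is assessed with a hand-rolled linear
    discriminant classifier, and label differences are tested with one-way
    ANOVA plus Bonferroni-corrected pairwise tests. A synthetic cohort
    generator with a crouch-gait severity parameter and controllable error
    tiers makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
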