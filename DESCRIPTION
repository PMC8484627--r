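Package: contouraffect
Title: Contour Features and Affective Judgements of Visual Scenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how mid-level contour statistics of line
    drawings relate to emotional judgements of scenes.  Computes pixel-weighted
    orientation, length and angularity histograms of polyline drawings;
    regresses mean valence ratings on the resulting feature vectors;
    constructs abstract scene stimuli with controlled combinations of contour
    length, angularity and orientation; and analyses four-alternative
    forced-choice valence/threat judgements with random-intercept logistic
    regression and likelihood-ratio tests.  A synthetic-data module generates
    controlled line drawings, rating datasets from a known linear model, and
    simulated choice sessions for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2,
    glmmTMB,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
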