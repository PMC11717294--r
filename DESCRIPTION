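Package: chopgrip
Title: Objective Video-Based Assessment of Children's Chopstick Grip
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for objective assessment of how children hold chopsticks
    from single-camera video. Implements tape-color chopstick detection with
    previous-frame carry-forward, geometric feature extraction from 21-point
    hand landmarks (fingertip-to-chopstick distances), time-series
    summarization with the CO_f1ecac first-1/e autocorrelation-crossing
    feature, and a decision-tree classifier separating the traditional
    (four-finger) grip from nontraditional grips. A synthetic hand-kinematics
    simulator generates labelled landmark and chopstick sequences for four
    grip archetypes, rendered frames for detection testing, and synthetic
    questionnaire tables with known effect sizes. Survey statistics cover
    DCDQ scoring, grip tallies, Fleiss' kappa inter-rater agreement,
    Lilliefors normality screening, multinomial logistic regression with
    odds ratios and sandwich standard errors, and Nagelkerke pseudo-R2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    rpart,
    nortest,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    nnet,
    optparse
Config/testthat/edition: 3
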