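Package: rsnlabel
Title: Automatic Labeling of Resting-State Networks from ICA Spatial Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies per-subject independent-component (IC) t-statistic
    maps from resting-state fMRI into canonical resting-state networks
    (auditory, visual, default-mode, sensorimotor, executive control).
    Provides block-mean volume downsampling to an R x R x R feature grid,
    a template spatial-correlation classifier, a one-vs-all perceptron,
    and a naive Bayes classifier on Z-score-discretized features, together
    with the tuning and leave-one-subject-out cross-validation protocol
    (confusion matrices, per-class metrics, binomial test against chance),
    a seedable synthetic IC-map generator for end-to-end testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    png,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    rpart,
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
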