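Package: gaitfuse
Title: Multi-Classifier Fusion for Gait Pattern Transition Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Hybrid feature-level and decision-level information fusion for
    recognizing gait pattern transitions from multichannel kinematic signals.
    Provides a seeded synthetic-data generator for band-limited multichannel
    gait trials, a 462-dimension time- and frequency-domain feature bank,
    two-stage MRMR-BMSF feature selection, five base classifiers (BP network,
    1-nearest-neighbour, and linear/RBF/polynomial support vector machines)
    behind a uniform probability-score interface, eight classifier-output
    fusion rules centred on Dempster-Shafer evidence combination, and the
    two-stage repeated cross-validation protocol with missing-feature-group
    robustness analysis used to select the final ensemble.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    nnet,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
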