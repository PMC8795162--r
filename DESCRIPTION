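Package: splitsite
Title: Multi-Site Split Learning with Cut-Layer Feature-Map Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates multi-site split learning, a collaborative training
    protocol in which several end-systems (e.g. hospitals) each hold one
    hidden layer of a deep network and transmit only cut-layer feature maps
    to a central server that concatenates them and trains the remaining
    layers. Provides the three reference split architectures (a small
    convolutional classifier, a VGG19-style split classifier and a small
    regression network), largest-remainder data partitioning across
    end-systems for studying data imbalance, synthetic generators for
    two-class grayscale medical-style images and Friedewald-structured
    cholesterol tables, evaluation metrics (accuracy, binary cross-entropy,
    MSE, RMSLE), a quantitative feature-map leakage audit, and a seeded
    experiment grid runner over end-system counts and split ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
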