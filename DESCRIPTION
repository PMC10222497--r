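Package: semicor
Title: Semi-Correlation QSAR Classifiers from SMILES-Based Optimal Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds binary-endpoint quantitative structure-activity
    relationship (QSAR) classifiers by semi-correlation: SMILES strings
    are tokenized into single, pair and triple attributes whose
    correlation weights are fitted by Monte Carlo coordinate search
    against target functions optionally augmented with the index of
    ideality of correlation (IIC).  Models are trained on a four-way
    random split (active training, passive training, calibration,
    validation) with an overtraining guard on the calibration set, and
    validated through the system of self-consistent models: a matrix of
    cross-split Matthews correlation coefficients summarised by its
    off-diagonal mean and dispersion.  Includes a planted-signal
    synthetic data generator so the full pipeline is testable without
    external data, plus a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
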