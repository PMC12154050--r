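Package: connectocoh
Title: Coherence-Based Time-Graph Images and Convolutional Classifiers for Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts multichannel EEG recordings into coherence-based
    time-graph grayscale images (one magnitude-squared-coherence adjacency
    matrix per sliding window, upper triangle flattened into a pixel column,
    columns tiled over time), and classifies the resulting images with a
    compact convolutional network or a shallow one-dimensional residual
    network trained under leakage-free subject-wise cross-validation.
    Includes a synthetic coupled-source EEG generator with planted,
    class-specific coherence structure so the whole pipeline can be exercised
    and validated without any external data, plus EDF input/output and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pROC,
    png,
    signal,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
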