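Package: imetk
Title: Recording-Quality Metrics and Micromotion Strain Modelling for
    Intracortical Microelectrodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking chronic intracortical microelectrode
    studies in rodents. Generates seeded synthetic multi-channel
    extracellular recordings with known ground truth; implements the
    standard recording-quality pipeline (band-pass filtering, common
    average referencing, rule-based artifact removal, threshold spike
    detection, snippet clustering) and five recording-quality metrics
    (percent channels with units, units per working channel, background
    noise level, unit peak-to-peak amplitude, signal-to-noise ratio);
    compares two animal groups over acute and chronic time ranges with a
    nested general linear model; and predicts micromotion-induced tissue
    strain around an implanted silicon shank with a three-dimensional
    linear-elastic finite-element model, including von Mises strain
    fields, joint normalization and lateral strain profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    mclust,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
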