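Package: topostat
Title: Group-Level Multivariate Topographic Statistics for Epoched EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group-level multivariate analysis of epoched multi-subject EEG in
    sensor space: distribution-of-significant-sensors maps, global field power
    (GFP) dynamics with windowed paired tests, topographic analysis of variance
    (TANOVA) based on the high-dimensional angle between condition topographies
    with three permutation-null strategies and temporal cluster or FDR
    correction, and sliding-window pattern classification with group-level
    sign-flip permutation inference against chance. Includes an HDF5 epochs
    container reader/writer, a synthetic multi-subject epochs generator with
    separable response-magnitude and topographic-pattern effects, result
    serialization, minimal plotting, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rhdf5,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    pROC,
    optparse
Config/testthat/edition: 3
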