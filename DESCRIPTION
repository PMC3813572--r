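Package: dtfnet
Title: Multivariate Effective Connectivity for Multichannel Neural Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and comparison of directed (effective) and bivariate
    (functional) connectivity in multichannel neural recordings. Fits
    multivariate autoregressive (MVAR) models, derives the spectral transfer
    matrix and the normalized Directed Transfer Function (DTF), and contrasts
    it with magnitude-squared coherence and synchronization likelihood.
    Includes surrogate-based significance thresholds (phase-randomization
    null), node-degree and true/spurious edge accounting against known ground
    truth, assortative-mixing module coupling matrices, and a synthetic-data
    module generating common-source, volume-conduction, MVAR and modular
    network recordings with known connectivity.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
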