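Package: megmetrics
Title: Spectral Shape, Band Power and Envelope Connectivity Metrics for
    Parcellated MEG with Permutation GLM Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes resting-state electrophysiological metrics from
    parcellated MEG source time courses: Welch power spectral density and
    canonical band powers, aperiodic/periodic spectral parameterisation
    (1/f exponent, oscillatory peaks, centre-of-energy oscillatory speed),
    and band-wise amplitude-envelope-correlation connectivity.  Group and
    ageing effects are tested with mass-univariate general linear models
    using max-t permutation family-wise error correction.  Includes a
    synthetic-cohort generator producing parcel time courses with known
    aperiodic, oscillatory and envelope-sharing ground truth for method
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
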