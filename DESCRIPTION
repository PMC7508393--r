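Package: ringdate
Title: Probabilistic Age Determination for Tree-Ring Series
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dating of tree-ring series when annual ring boundaries cannot be
    verified by crossdating, as in many lowland tropical samples. Each putative
    growth boundary carries an analyst-supplied probability of being annual;
    these probabilities are propagated recursively into a discrete age
    distribution for every boundary, from which expected ages, standard
    deviations and piecewise-linear 95% confidence limits are derived, together
    with radius-versus-age confidence curves. Also provides probabilistic
    versions of the classical dendrochronological series statistics (mean
    sensitivity, first-order autocorrelation, time-series variance and process
    standard deviation), expected-missing-boundary accounting with
    studentized-width outlier detection, scenario simulation, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
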