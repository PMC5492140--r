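Package: evoentropy
Title: Lognormal Stochastic-Process Models of Macroevolutionary Diversity
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the number of living species (or genera) through time as a
    lognormal stochastic process calibrated from five boundary parameters:
    start time and count, end time, end mean count and end standard deviation.
    Mean-value curve families (exponential/geometric Brownian motion, straight
    line, parabola, cubic with prescribed extrema, generic polynomial) are
    evaluated in closed form; the peak-locus construction attaches to every
    time instant the unique b-lognormal density whose peak rides the mean
    curve, and the sign-reversed, origin-anchored Shannon differential entropy
    of that family (EvoEntropy, in bits per individual) quantifies the
    evolutionary stage reached at each epoch.  EvoEntropy is exactly linear in
    time when the mean is exponential, mirroring the molecular clock.  A
    Monte-Carlo trajectory simulator, scenario configuration files and a
    command-line interface round out the toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
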