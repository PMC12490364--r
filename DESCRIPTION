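Package: coxbf
Title: Bayes Factors for Two-Group Cox Proportional Hazards Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes Bayes factors contrasting a null against an
    alternative hypothesis about the hazard ratio in two-group Cox
    proportional hazards regression, using Efron's approximation to the
    partial likelihood and Gaussian quadrature over a (possibly
    truncated) Normal prior on the log hazard ratio. When only published
    summary statistics are available, pseudo-raw survival datasets are
    reverse-engineered by particle swarm optimization so that their
    fitted summary statistics match the published ones, yielding a
    distribution of Bayes factors. A closed-form Savage-Dickey Normal
    approximation is included as a fast comparator, together with a
    synthetic survival-data generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    survival,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
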