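Package: heatexcess
Title: Probabilistic Classification of Excess Deaths During Extreme Heat Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a repeated-resampling case-control framework for
    probabilistically classifying individual deaths during an extreme hot
    weather event as probable excess or probable expected. The expected
    number of deaths is repeatedly sampled from the event-period case pool
    and compared with typical-weather controls in logistic regression
    models over many repetitions and trials; cases consistently selected
    into significant models are ranked as the most probable excess deaths.
    Includes the twelve univariate and multivariate modeling combinations,
    rank-stability diagnostics, a post-classification assessment suite
    (group comparisons, overlap and consensus analysis, daily death
    distributions), and a synthetic-cohort generator with known
    excess/expected ground truth for validating the method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
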