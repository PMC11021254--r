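Package: sdtroc
Title: Hierarchical Signal Detection Modeling of Confidence-Rating ROC Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing six-point confidence-rating recognition
    memory data under Gaussian signal detection theory. Builds cumulative
    confidence ROCs and estimates zROC slopes and intercepts by least
    squares, with principled handling of degenerate (vertical) zROCs.
    Fits equal-variance and three unequal-variance signal detection
    models, and a serial-position variant for Sternberg-style short-term
    recognition, to participant-level rating counts using hierarchical
    Bayesian inference with a differential-evolution MCMC sampler.
    Model comparison uses the widely applicable information criterion
    (WAIC) computed from trial-level pointwise log-likelihoods. Includes
    a hierarchical synthetic-experiment generator for study-test and
    Sternberg list designs so the whole pipeline can be exercised and
    validated by parameter recovery without access to raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
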