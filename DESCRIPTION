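Package: rhythmrep
Title: Bayesian Observer Modelling of Temporal Pattern Reproduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the temporal order of short auditory
    sequences shapes their reproduction. Implements a generative Bayesian
    observer for four-interval sequences in which the ensemble prior is a
    weighted average of the first interval and the design mean, sensory noise
    follows Weber's law scaled by a per-condition volatility factor, and each
    reproduced interval is the reliability-weighted fusion of prior and
    sensory estimate. Provides the experimental design generator (accelerating,
    decelerating and random sequences built from two fixed interval sets), a
    trial-level synthetic-data simulator, the behavioral summary pipeline
    (outlier exclusion, central-tendency slopes, condition means and
    reproduction variability, first/last-interval analyses), and a two-stage
    fitting procedure (maximum a posteriori by default, MCMC via 'rjags'
    optionally) with parameter-recovery utilities and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    optparse
Suggests:
    rjags,
    coda,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
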