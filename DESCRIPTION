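Package: effortalloc
Title: Cost-Evidence Accumulation Modelling of Effort Allocation Behaviour
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing effort allocation in incentivised handgrip
    tasks. Segments grip-force recordings into effort and rest epochs, fits a
    bounded cost-evidence accumulation model in which effort and rest
    durations equal the amplitude of cost-evidence variations divided by its
    accumulation and dissipation slopes, enumerates the admissible space of
    incentive and difficulty modulations, approximates model evidence with a
    variational Laplace scheme, performs group-level random-effects Bayesian
    model selection, quantifies between-group parameter modulations with
    nested delta models, and validates the whole chain with seeded
    parameter-recovery simulations and synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
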