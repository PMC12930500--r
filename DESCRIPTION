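Package: circlearn
Title: Minimal Gene Circuits for Nonassociative Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic simulation and analysis of minimal synthetic gene
    regulatory circuits that implement nonassociative learning behaviors:
    habituation (an incoherent feed-forward loop whose output peaks shrink
    under repeated stimulation), sensitization (a double-repression cascade
    whose peaks grow), a hybrid circuit showing sensitization followed by
    habituation, and a massed-spaced learning circuit in which temporally
    spaced stimulation outperforms a single massed stimulus. Provides
    pulse-train stimulation protocols, a discontinuity-aware fixed-step
    integrator, per-interval peak extraction with log2 fold-change learning
    metrics, a closed-form impulsive (Dirac-train) approximation layer for
    the memory species, and parameter-space sweeps producing phase-diagram
    style maps of learning strength. All results are tibbles that compose
    with the pipe; plotting uses ggplot2.
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
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
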