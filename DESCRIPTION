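Package: unfoldkin
Title: Single-Turnover Kinetics of Processive Protein Unfolding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of single-turnover stopped-flow fluorescence experiments
    that probe processive protein unfolding by AAA+ motor proteins such as
    ClpB acting on RepA-Titin substrates. Implements the n-step sequential
    kinetic signal model (gamma-chain arrival convolved with terminal
    dissociation), a model-independent peak-time analysis relating substrate
    length to motor arrival time, global multi-trace nonlinear least-squares
    estimation of the kinetic step-size and unfolding rate constant, and the
    processivity algebra linking per-step continuation probability, step-size,
    and processivity in amino acids. A synthetic stopped-flow data generator
    with the same statistical structure supports parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
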