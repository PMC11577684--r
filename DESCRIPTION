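Package: seamless
Title: Seamless Phase I/II Platform Trial Design with a Time-to-Event
    Efficacy Endpoint
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and evaluation of a randomized Bayesian seamless
    phase I/II platform trial design for single-agent and dual-agent
    dose-escalation with a time-to-improvement efficacy endpoint.
    Implements a two-parameter logistic dose-toxicity model with overdose
    control, a four-parameter dual-agent combination model with an
    interaction odds multiplier, sequential efficacy testing based on the
    Cox partial likelihood under a two-point prior on the hazard ratio,
    simulation-based calibration of stopping boundaries, control-arm
    sharing across a platform, and a scenario engine producing operating
    characteristics (recommendation frequencies, error rates, sample
    sizes).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
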