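Package: thyrodose
Title: Model-Based Levothyroxine Dose Guidance with Robust Discrete-Time Control
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and controller-design toolkit for automatic oral
    levothyroxine (LT4) dosing in hypothyroid patients.  Provides a two-state
    pharmacokinetic model of exogenous T4 and free thyroxine (FT4) with
    Michaelis-Menten TSH-driven endogenous production, exact closed-form
    simulation under impulsive daily dosing, least-squares identification of
    patient-specific parameters, impulse-invariant discretization and
    pole-placement synthesis of a first-order discrete dose controller with a
    rate limiter, Jury-Pavlidis robust Schur-stability verification over an
    elimination-rate uncertainty interval, a guideline-constrained closed
    dosing loop (200 ug/day ceiling, 12.5 ug quantum, bounded per-visit
    steps, euthyroid dead band), and a seeded virtual-patient cohort
    simulator with circadian FT4 ripple and TSH negative feedback.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
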