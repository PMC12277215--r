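Package: exodesign
Title: Two-Level Design Optimization for Passive Assistive Exoskeletons
Version: 0.1.0
Authors@R: person("exodesign", "maintainers", email = "exodesign@example.org",
    role = c("aut", "cre"))
Description: A desk-scale platform for optimizing the design of passive
    assistive wearable devices by nesting a controller-optimization loop
    inside a design-optimization loop. The inner loop tunes a parametric
    planar gait (CMA-ES) on a reduced-order inverse-dynamics model; the
    outer loop searches a mixed continuous-categorical device space
    (damping coefficient and clutch engagement pattern of a knee damper)
    with Gaussian-process Bayesian optimization, validated against
    brute-force grid evaluation. Includes a five-phase gait segmentation
    state machine, knee-load and cost-of-transport metrics,
    stride-normalized curve reporting, and synthetic fixtures (scripted
    leg-state traces, baseline gait presets, a known-optimum noisy design
    surface) so every stage is testable without external data.
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
    withr
Config/testthat/edition: 3
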