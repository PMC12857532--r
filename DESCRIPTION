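Package: vmatrl
Title: Tandem Reinforcement Learning for VMAT Machine Parameter Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale research toolkit for volumetric modulated arc
    therapy (VMAT) machine parameter optimization by tandem reinforcement
    learning. Two cooperating stochastic policies -- a multi-leaf collimator
    (MLC) aperture network acting sequentially per control point and a
    monitor-unit (MU) network refining all control points at once -- are
    trained with proximal policy optimization and generalized advantage
    estimation against a dose-volume-histogram constraint-scaled reward.
    Includes seeded synthetic pelvic phantoms, a machine/arc model with
    deliverability checking, an analytic beamlet dose engine with D95
    renormalization and gamma-index comparison, behavioral-cloning
    initialization, cohort evaluation with rank-sum statistics, and a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
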