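Package: esportkin
Title: Upper-Limb Kinematics of Esports Players from Tri-Axial Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes tri-axial accelerometer recordings (hand, forearm, arm)
    of computer-mouse users into per-session kinematic metrics and cohort-level
    genre comparisons. Implements outlier replacement, gravity zeroing,
    Butterworth band-pass filtering and double trapezoid integration; root-mean-
    square global acceleration, limb-segment acceleration ratios, velocity
    zero-crossing counts, cumulative hand travel distance, and 95% confidence
    ellipses of hand displacement; one-way ANOVA with eta-squared and Fisher
    LSD post hoc tests, chi-square contingency analysis with Sidak correction,
    and log-transform bootstrap confidence intervals. Ships a synthetic session
    generator with analytic ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    data.table,
    jsonlite,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
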