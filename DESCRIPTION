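Package: gaitstab
Title: Gait Stability Metrics and User Perception of Powered-Prosthesis
    Control Faults
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes sagittal-plane gait stability metrics (step length and
    width, margin of stability via the extrapolated centre of mass,
    inclination angle, whole-body angular momentum, knee momentum, A-P centre
    of pressure progression, vertical centre-of-mass displacement) from
    segment kinematics and insole pressure recordings of powered-prosthesis
    walking, quantifies per-stride deviation from a subject's normal-gait
    template as excursion-normalised RMSE (N-RMSE), merges disturbance
    conditions with one-dimensional permutation statistical parametric
    mapping, and models the user's ordinal perception of control-fault
    disturbances with Kendall correlation and a quadratic binomial GLM.
    Includes a synthetic disturbed-gait generator with full ground truth so
    the complete analysis runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
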