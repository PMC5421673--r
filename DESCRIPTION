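Package: anklestiff
Title: EMG-Driven Estimation of Ankle Joint Stiffness with a Square-Root
    Cubature Kalman Filter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sagittal-plane neuromusculoskeletal model of the human lower
    extremity (thigh, shank, foot) driven by surface-EMG envelopes, with a
    square-root cubature Kalman filter that fuses segmental orientation
    measurements to estimate knee and ankle joint angles, angular rates,
    torques and ankle quasi-stiffness. Includes muscle-path geometry with
    fourth-order polynomial moment-arm tables, Hill-type muscle-tendon
    dynamics, Euler-Lagrange multibody dynamics with nonlinear passive
    joint torques, a forward simulator for fully synthetic in-silico
    experiments, and EMG envelope / band-limited differentiation signal
    processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
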