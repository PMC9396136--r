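Package: squatmech
Title: Lower-Limb Biomechanics of the Barbell Squat with Rearfoot Valgus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end musculoskeletal analysis chain for comparing
    barbell-squat lower-limb mechanics between rearfoot-valgus and
    normal-foot groups: marker-driven inverse kinematics on a reduced
    right-leg linkage, recursive Newton-Euler inverse dynamics,
    static-optimization muscle force estimation, medial/lateral
    tibiofemoral contact-force decomposition by frontal-plane moment
    balance, EMG processing (band-pass, RMS envelope, MVC normalization)
    for model validation, squat-cycle segmentation and 101-point time
    normalization, and group statistics combining discrete t-tests with
    one-dimensional statistical parametric mapping over whole cycle
    curves.  A seeded synthetic squat-cohort generator (markers, ground
    reaction forces, EMG) with known ground truth makes every stage
    testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    quadprog,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
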