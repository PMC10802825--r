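Package: vtcycle
Title: Cycle-Length Variability Analysis of Device-Recorded Ventricular Tachycardia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing beat-to-beat cycle-length (CL) series of
    ventricular tachycardia (VT) episodes stored on implantable cardioverter
    defibrillators. Computes time-domain variability metrics (SD, RMSSD,
    NN50/pNN50, TINN), Poincare dispersion (SD1/SD2),
    initiation-to-shortest-CL dynamics and a first-order autoregressive
    stability fit on the first 10 cycle lengths; compares spontaneously
    terminating against sustained episodes with parametric or rank-based
    tests; and predicts spontaneous termination with a feature-selected,
    cross-validated random forest. Includes a calibrated synthetic episode
    generator so the full pipeline is testable without access to clinical
    device data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    randomForest,
    pROC,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    lattice,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
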