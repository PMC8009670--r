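Package: picquant
Title: Persistent Inward Current and Frequency-Current Analysis of
    Motoneuron Ramp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of persistent inward currents (PICs) and
    frequency-current (F-I) properties of spinal motoneurons from triangular
    voltage-clamp and current-clamp ramp recordings. Implements linear leak
    fitting and subtraction, PIC amplitude/onset/peak/end extraction, dV/dt
    spike-threshold detection, subprimary/primary range segmentation and F-I
    gains, assembly of a 21-feature per-cell table, and an estimation-statistics
    layer (Hedges' g with BCa bootstrap confidence intervals, Welch's t,
    regressions against age, ANCOVA, PCA). A conductance-based synthetic
    motoneuron simulator generates voltage- and current-clamp ramp responses
    with known ground truth so that every stage of the pipeline is testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    boot
Config/testthat/edition: 3
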