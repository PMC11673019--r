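Package: corneavoct
Title: Corneal Biomechanics from Vibrational Optical Coherence Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing mechanovibrational spectra of the cornea
    measured by vibrational optical coherence tomography (VOCT). Provides a
    seeded synthetic-data generator for weighted-displacement versus frequency
    spectra and labelled control/keratoconus and human/porcine cohorts;
    spectrum normalization, resonant-peak detection and tissue-component band
    assignment; an empirical resonant-frequency to elastic-modulus calibration
    with grid-resolution uncertainty propagation; machine-learning localization
    of the Bowman's-layer resonance by a per-frequency two-cluster Gaussian
    mixture scan and a leave-one-frequency-out support-vector ablation; and an
    axisymmetric linear-elastic finite-element model of corneal deflection
    under intraocular pressure for healthy and keratoconic geometry, verified
    against the clamped-plate closed form.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    e1071,
    ggplot2,
    jsonlite,
    mclust,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
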