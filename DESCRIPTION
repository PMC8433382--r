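Package: motorfreq
Title: Frequency-Based Separation of Motor Planning and Execution from
    Continuous Behavior and Spiking Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for separating motor planning from motor
    execution in continuous, minimally repetitive behavior recorded together
    with cortical spiking activity. Provides a synthetic session generator
    with ground truth (sub-movement behavior, velocity-modulated Poisson
    units, raw 30 kHz voltage traces), threshold-based spike snippet
    extraction and seed-and-neighborhood sorting, activity-weighted
    distributions and velocity-modulation metrics, population-correlation
    time constants, subtractive-Gaussian band-pass filtering with rectified
    envelopes, kernel-based encoding and frequency-swept two-point decoding,
    output-null/output-potent state-space analysis, phase-amplitude
    cross-frequency coupling, and dependence-corrected statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
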