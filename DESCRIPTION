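Package: multiteer
Title: Independent Barrier-Resistance Monitoring from Impedance Spectra in
    Multi-Barrier Culture Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for monitoring epithelial and endothelial barrier integrity
    in multi-barrier in vitro culture models from electrochemical impedance
    spectroscopy (EIS). Implements the four-element equivalent circuit
    [R1(R2C2)C1] and its complex nonlinear least-squares fit to recover the
    barrier resistance R2 per working electrode, with per-well aggregation over
    electrode replicates; a 2D frequency-domain electro-quasistatic
    finite-element forward solver with thin-layer surface-impedance barriers
    that reproduces the selectivity of a conformable electrode device placed on
    either face of a stacked gut-immune-vasculature model; EVOM TEER
    conversion; treatment-experiment statistics (Welch/Student t-tests, one-way
    ANOVA with Tukey HSD); and a synthetic-data generator emulating the
    measurement campaign so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    Matrix,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
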