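Package: psdcal
Title: Calibration and Characterization Pipeline for Plastic Scintillation
    Dosimetry in HDR Brachytherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational pipeline for calibrating and characterizing a
    plastic scintillation detector (PSD) used for in vivo dosimetry in
    Ir-192 high-dose-rate brachytherapy. Implements away-along reference
    dosimetry in the TG-43 formalism (table interpolation on
    inverse-square-flattened grids, line-source geometry function, source
    decay), the TRS-398-derived mini-phantom-to-full-scatter calibration
    chain (quality factors, the full-scatter factor F, absorbed dose to
    water), stem-effect subtraction and signal normalization, angular and
    temperature dependence characterization with a linear temperature
    model, GUM-style Type A/Type B uncertainty budgets, and a seeded
    synthetic-data generator that emulates PSD and dummy-probe
    measurement sessions with injected, known dependences.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
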