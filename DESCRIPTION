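Package: collarch
Title: Collagen Architecture and Biomechanics of Engineered Tendon
Version: 0.1.0
Authors@R:
    person("Adam", "Reeve", email = "collarch@users.noreply.github.com",
           role = c("aut", "cre"))
Description: Quantitative analysis pipeline for tissue-engineered tendon:
    grey-level co-occurrence matrix (GLCM) texture curves and partial least
    squares discriminant analysis (PLS-DA) of second-harmonic-generation-like
    collagen images, structure-tensor fibre orientation and alignment
    quantification, transmission-electron-microscopy-style fibril diameter
    morphometry, and tensile/viscoelastic mechanics (stress, strain,
    hysteresis, energy loss, stress-relaxation rate, Young's modulus).
    Includes a seeded synthetic-data generator producing fibre-field images,
    fibril cross-section masks and standard-linear-solid load traces with
    known ground truth, so the full pipeline is testable without laboratory
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
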