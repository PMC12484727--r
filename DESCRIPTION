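Package: brainmodes
Title: Finite-Element Modal Analysis of Multi-Compartment Brain Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the mechanical resonance modes of the brain with
    the finite element method at desk scale. Generates synthetic
    multi-compartment head phantoms (white matter, gray matter,
    cerebrospinal fluid, skull, optional neck and spine cylinders),
    assembles sparse stiffness and mass matrices for heterogeneous
    isotropic linear elasticity on linear tetrahedra, extracts the lowest
    eigenmodes with a shift-invert Lanczos solver, and compares modal
    results with the Modal Assurance Criterion (MAC) and the Normalized
    Relative Frequency Difference (NRFD). Also includes a Leading
    Eigenvector Dynamics Analysis (LEiDA) style extractor of recurring
    phase-alignment modes from synthetic BOLD-like signals, and
    experiment drivers for model-complexity, boundary-condition and
    CSF-stiffness comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
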