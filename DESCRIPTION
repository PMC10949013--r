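Package: nanoqspr
Title: Periodic-Table Descriptor QSPR Modeling of Metal-Oxide Nanoparticle
    Zeta Potential and Cell Damage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage nano-QSPR analysis for metal-oxide nanoparticles:
    periodic-table descriptors computed from chemical formulas and an
    element-constant table, a partial-least-squares model for zeta
    potential whose predictions are imputed as a descriptor into a
    cell-damage model, external validation metrics (Q2F1, Q2F2, Roy rm2),
    Y-randomization, the Williams-plot applicability domain, and
    similarity-based read-across with Euclidean, Gaussian-kernel and
    Laplacian-kernel weighting. Includes a synthetic-data generator that
    emulates the zeta-potential and cell-damage dataset designs so every
    stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
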