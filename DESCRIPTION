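Package: podoactin
Title: Actin Cytoskeleton Stability in Kidney Podocyte Foot Processes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multiscale analysis of actin cytoskeleton stability in kidney
    podocyte foot processes. Implements a minimal three-state kinetic model
    of actin exchange between monomers, filaments and crosslinked bundles,
    with phase-plane analysis (nullclines, equilibria, stability, regime
    classification), a two-compartment extension with a shared, rapidly
    diffusing monomer pool, and a reaction-diffusion version on a
    procedurally generated idealized podocyte geometry (cell body, major
    processes and foot processes matched to measured morphometric targets).
    Includes perturbation scenarios for bundling and polymerization rates,
    per-foot-process effacement detection, and asynchrony and
    pattern-divergence diagnostics for the chaotic spatiotemporal collapse
    of actin bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
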