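Package: AbetaKinetics
Title: Discrete-Time Kinetic Modelling of Beta-Amyloid Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a discrete-time kinetic model
    of beta-amyloid aggregation, in which monomers produced by a
    Beverton-Holt source aggregate irreversibly through dimers and higher
    intermediates into oligomers. Provides the closed-form update map and an
    increment-form verification oracle, the extinction and coexistence
    equilibria with fixed-point diagnostics, analytic and numerical Jacobians,
    Gershgorin-disk stability certificates alongside eigenvalue
    classification, a destabilization (intervention) criterion, an inversion
    formula for the oligomer aggregation number, parameter scans, and a
    seeding experiment measuring time to oligomer accumulation. Includes a
    config-driven command-line interface and a reproducible random-parameter
    fixture generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    pracma
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'model-core.R'
    'equilibrium.R'
    'stability.R'
    'intervention.R'
    'io.R'
    'random-parameters.R'
    'cli.R'
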