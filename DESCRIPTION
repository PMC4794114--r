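Package: designspacer
Title: Automated Design Space Analysis of Power-Law Biochemical Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates the qualitatively distinct phenotypes (the phenotypic
    repertoire) of nonlinear biochemical models written as generalized mass
    action (GMA) systems, without requiring prior parameter values. Each
    phenotype corresponds to an S-system obtained by keeping one dominant
    positive and one dominant negative term per equation; its validity region
    in log-parameter space is a convex polytope tested by linear programming,
    and a slack-maximizing interior parameter set is generated for every
    valid phenotype. Local dynamics are classified from reduced Jacobian
    eigenvalues (stable, exponentially unstable, oscillatory unstable),
    design space slices are rasterized into region and stability maps, and
    ensembles of phenotypes can be co-localized or ordered within a
    two-dimensional slice. Includes constructors for a 16-member family of
    two-gene activator-repressor circuits and a screen for oscillator
    designs, plus a plain-text model format, rational-to-GMA recasting, and
    seeded synthetic model generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
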