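Package: fitscape
Title: Nonlinear Fitness Landscapes for Inverse Protein Folding via
    Reduced Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs global nonlinear fitness functions for protein
    sequence design (inverse protein folding). Proteins and sequence
    decoys are represented as 210-dimensional residue-contact count
    vectors derived from Delaunay-filtered heavy-atom contacts, length
    normalized by a fitted contacts-versus-length regression. A reduced
    support vector machine with a rectangular Gaussian kernel is trained
    by a finite Newton method with Armijo line search, using iterative
    hard-example selection strategies to build the data and basis sets.
    Includes gapless-threading and composition-preserving swap decoy
    generators, F-beta evaluation for the imbalanced native/decoy
    classification task, and synthetic-data generators for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    bio3d,
    withr,
    yaml
Suggests:
    quadprog,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
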