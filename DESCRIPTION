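Package: paretoshell
Title: Pareto Optimality Analysis of Coiled-Shell Morphospace
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the morphospace of logarithmic-spiral
    (Raup W-D-S) shells under multi-objective (Pareto) optimality.
    Provides shell-geometry performance functions (shell-material economy,
    growth, and a pluggable hydrodynamic-drag surface), Pareto-front
    construction on trait grids, enclosing-polytope fits (minimum-volume
    simplexes and principal convex hull / archetypal analysis),
    randomization statistics for polygonality and triangle similarity,
    distance-to-archetype enrichment tests, Westermann-style ternary
    projection with distortion diagnostics, and a synthetic genus-table
    generator with known ground truth for validating every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
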