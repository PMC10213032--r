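Package: mycelia
Title: Lattice-Free Simulation and Density Phases of a Growing Hyphal Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based, lattice-free simulation of a two-dimensional fungal
    mycelium growing as a binary tree with lateral branches, calibrated on
    measured branching statistics of Podospora anserina: apical dominance with
    base-2 exponential branch spacing, a two-population (burst plus uniform)
    lateral branching process, spontaneous curvature with tunable chirality,
    and a saturating tip-velocity ramp. Provides the spatial-graph geometry
    layer (vertex classification, crossing detection, tortuosity), the
    apex-cloud inertia-tensor density observable rho = N1/(r1*r2) with
    bootstrap uncertainties and detection of the density minimum separating
    the growth phases at t_min = n/(omega*ln 2), and the accompanying
    statistical toolkit (base-2 exponential and mixture fits, early power-law
    fits, binomial orientation tests with Bonferroni correction, one-way
    ANOVA and mean-centred Levene tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
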