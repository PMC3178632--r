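Package: parabd
Title: Brownian Dynamics of ParABS-Mediated Chromosome Translocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained Brownian dynamics simulator of bacterial
    chromosome segregation by the ParABS system.  A ParB-decorated polymer
    (the ParB-parS-ori complex) binds a cross-linked bundle of ParA
    filaments anchored at a cell pole, stimulates ATP hydrolysis, and is
    pulled across the cell as the bundle disassembles from its tips --
    a self-diffusiophoretic mechanism in which ParB moves up the ParA
    concentration gradient it creates.  The package provides the
    bead-spring force field (excluded volume, bonds, crosslinks, bending,
    polarization alignment, helical site placement, and oriented
    ParA-ParB binding), an overdamped Langevin integrator coupled to
    stochastic hydrolysis/depolymerization/severing chemistry, scenario
    presets for the model variants (side- vs tip-binding, tip-only
    disassembly vs severing, unanchored bundles, sparse bundles, external
    load), trajectory and observable I/O, and the companion analytic
    theory (polymer stretching relaxation time, maximum disassembly rate,
    three-regime velocity law, Kramers detachment time and force, and the
    unanchored force balance).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    rlang,
    withr,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
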