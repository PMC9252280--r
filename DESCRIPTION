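Package: sumodl
Title: Steady-State Model of Dorsal SUMOylation in Toll/NF-kB Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Equilibrium mass-action model of the Drosophila Dorsal (NF-kB)
    signaling module in which a small SUMOylated fraction of Dorsal competes
    with the unSUMOylated pool for dimerization, Cactus (IkB) sequestration,
    nuclear partitioning and promoter binding. The package enumerates the
    molecular species of the model, solves the steady-state conservation
    equations for the two free cytoplasmic monomer concentrations (with an
    independent nested-bisection oracle), computes reporter expression under
    wild-type (partially SUMOylated) and SUMO-conjugation-resistant (SCR)
    conditions, and runs parameter-ratio sweeps, robustness grids and seeded
    random parameter ensembles over the ratio of SCR to wild-type expression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
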