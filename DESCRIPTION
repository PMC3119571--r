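Package: erbbscale
Title: Multiscale Analysis of ErbB Kinase Activation and Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trajectory-level statistics for ErbB family kinase domains
    (principal component analysis of C-alpha fluctuations, persistent
    hydrogen-bond and salt-bridge interaction networks with survival
    fractions, water-density-fluctuation hydrophobicity with solvent
    accessible surface area and quadrant classification) together with a
    mass-action ordinary-differential-equation model of ErbB/EGFR receptor
    signaling covering oncogenic kinase-domain mutants, the inhibitor
    lapatinib, ErbB3-mediated resistance scenarios, and local and global
    parameter sensitivity analysis. Includes a curated static knowledge
    base (subdomain residue maps, clinically identified mutation catalog,
    persistent-interaction tables) and synthetic-data generators with full
    ground truth for every analysis path.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    deSolve,
    jsonlite,
    lhs,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
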