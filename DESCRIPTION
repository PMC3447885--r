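Package: zincluster
Title: Zinc-Thiolate Cluster Stoichiometry, Connectivity and Topology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for characterizing trinuclear zinc-thiolate (Zn3Cys9)
    clusters of CXC and pre-SET domains: metal-binding stoichiometry from
    native electrospray mass spectrometry peaks, completion of partial
    metal-to-cysteine connectivity maps from 1H-113Cd correlation data by
    exhaustive constraint satisfaction, per-residue NMR observables
    (chemical-shift perturbation, steady-state heteronuclear NOE with
    propagated errors, hydrogen-deuterium exchange protection classes),
    NOE restraint bookkeeping and tetrahedral metal-coordination restraint
    generation, structure-side cluster detection, topology fingerprinting,
    superposition and ensemble RMSD, and a variable-gap consensus scanner
    for the CXC superfamily. Includes synthetic-data generators with known
    ground truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    jsonlite,
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
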