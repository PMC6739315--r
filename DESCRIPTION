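Package: mechabm
Title: Hybrid Mechanical/Agent-Based Simulation of Integrin-ERK
    Mechanotransduction in an Osteoblast
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A hybrid multiscale simulator coupling a closed-form
    spherical-inclusion mechanical model of cell/extracellular-matrix (ECM)
    interface stress under far-field shear with a particle-based stochastic
    agent model of integrin-initiated ERK mechanotransduction and osteogenic
    protein deposition in a spherical osteoblast. Integrins carry
    mechanosensitivity thresholds (homogeneous sensitive or ultrasensitive
    populations, or heterogeneous mixtures); forces computed per integrin
    each simulated second drive a FAK-Ras-Raf-MEK-ERK cascade, Runx2-driven
    transcription, translation and secretion of matrix proteins that stiffen
    the ECM and feed back on the transmitted force (mechanoreciprocity).
    Includes dynamics observables (E_max, EC50, phase segmentation,
    mechanical-memory baselines, deposition rates), replicate management
    with seeded reproducibility, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
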