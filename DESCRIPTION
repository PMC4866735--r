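Package: mtident
Title: EMG-Driven Muscle-Tendon System Identification for Walking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates muscle activations from surface EMG with a Bayesian
    drive filter, forward-simulates Hill-type muscle-tendon units over
    prescribed gait kinematics, assembles sagittal-plane joint moments,
    computes Umberger metabolic rates and the metabolic cost of transport,
    identifies muscle-tendon morphological parameters by dual-objective
    (metabolic vs. kinetic) evolutionary optimization, and selects an
    optimal Pareto solution from the per-muscle metabolic budget. A
    synthetic-gait module generates complete datasets with known ground
    truth so the whole pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
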