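Package: fabflex
Title: Fab Crosslinker Rigidity, Interface Stability, and SAXS Shape Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural-analysis toolkit for comparing how antibody Fab dimers
    crosslink cell-surface receptors. Implements domain-vector Fab-Fab angle
    statistics over molecular-dynamics trajectories, contact-persistence and
    linear-interaction-energy (LIE) stability scoring, shared-atom rigid-body
    grafting of receptor-crosslinker-receptor assemblies with transmembrane-vector
    angle measurement, and a small-angle X-ray scattering (SAXS) analysis stack:
    Guinier fitting, dimensionless Kratky transforms, pair-distance distributions,
    Porod volume and mass, Debye model profiles, chi-square model-to-data fitting,
    concentration-series merging, normalized spatial discrepancy, and simplified
    ensemble selection. A synthetic-data module generates structures,
    trajectories, energy series, and scattering curves with known ground truth so
    every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    pracma,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
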