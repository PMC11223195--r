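Package: tmtriad
Title: Kink, Contact and Hydrogen-Bond Analysis for Transmembrane
    Receptor-Adaptor Helix Bundles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trajectory analysis for three-chain transmembrane helix
    assemblies of the TREM2/DAP12 type: per-frame helix kink angles from
    four-residue C-alpha vectors with binned mode statistics, residue-level
    contact maps at C-alpha and all-atom resolution with persistence
    filtering and cross-system consensus merging, geometric hydrogen-bond
    and salt-bridge occupancy statistics, and interaction-type
    classification of interface residue pairs. Includes a synthetic
    helix-bundle generator that produces multi-model PDB trajectories with
    fully known geometric ground truth (programmable kinks and per-frame
    hydrogen-bond occupancy schedules) for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
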