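Package: parafold
Title: Parametric Backbone Building and Fitting for Regular Biomolecular Folds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds idealized all-backbone models of geometrically regular
    biomolecular folds (alpha-helical coiled coils, collagen triple helices,
    helix-pair solenoid repeat proteins and B-form DNA duplexes) from small
    sets of geometric parameters, and fits those parameters to target
    structures with a bounded differential-evolution optimizer scored by
    superposed backbone RMSD. Structures are held in a lightweight
    hierarchical atom/residue/chain container with PDB input and output,
    rigid-body manipulation, torsion-angle chain building, Kabsch
    superposition and RMSD100 length normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    bio3d,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
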