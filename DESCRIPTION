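Package: ribocar
Title: Geometry and Statistics for the Ribosome CAR mRNA Interaction Surface
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing the ribosome decoding-centre interaction
    surface formed by the stacked bases C1054 and A1196 of the small-subunit
    rRNA and the guanidinium group of ribosomal protein S3 arginine R146 (the
    CAR surface) in molecular-dynamics trajectories. Provides multi-model PDB
    trajectory input/output, radius-shell subsystem extraction with onion-shell
    restraint masks, deterministic emission of a staged
    minimisation/heating/equilibration protocol, hydrogen-bond detection with
    Watson-Crick/Hoogsteen edge classification, base-stacking and edge
    centre-of-mass distances, backbone RMSD, per-run time-course extraction and
    binning, multi-run aggregation with Welch tests, contact-frequency maps,
    and a synthetic-trajectory generator with scripted bond schedules for
    validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
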