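Package: hjdimer
Title: Transition-Dipole Geometry and Excitonic Coupling of Dye Dimers
    on DNA Holliday Junctions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of molecular-dynamics trajectories of cyanine dye
    dimers covalently tethered to DNA four-arm (Holliday) junctions.
    Computes per-frame transition-dipole geometry, the orientation
    factor kappa and inter-dye center distance R, excitonic hopping
    parameters J via the extended dipole approximation (with a
    point-dipole far-field oracle), dye-DNA residue-group contact maps,
    2-D orientation/coupling histograms, multi-trial summaries with
    H-like/J-like dimer classification, and junction arm descriptors
    (inter-duplex and twist angles). Includes a seed-controlled
    synthetic-trajectory generator with known ground truth so the whole
    pipeline is testable without molecular-dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
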