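Package: mechfret
Title: Calcium Response Classification and Substrate Strain Analysis for
    Locally Vibrated Cells on Elastic Gels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for ratiometric FRET calcium imaging of cells
    stimulated by a vibrating micro-probe inserted in an elastic substrate.
    Provides background subtraction and YPet/ECFP ratio computation, a
    three-band partition of the cell along the probe axis, classification of
    calcium responses as global, local or non-responsive, bead-based
    estimation of the substrate displacement field with finite-difference
    strain maps, multinomial estimation of per-condition response
    probabilities, and an exact (Freeman-Halton) contingency-table test for
    comparing conditions. A synthetic-data generator emulates the vibration
    experiment end to end (probe traces, bead image pairs, two-channel FRET
    movies with known ground truth) so the whole pipeline is testable without
    real microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    interp,
    jsonlite,
    mgcv,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
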