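Package: stereomd
Title: Prochiral-Face, Contact and Hydrogen-Bond Analysis of Enzyme MD Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to rationalize enzyme stereoselectivity from molecular-dynamics
    ensembles of ternary enzyme-cofactor-substrate complexes. Classifies, frame by
    frame, which prochiral face of a planar imine substrate is presented to the
    nearest nicotinamide hydride (with a bounded Cahn-Ingold-Prelog substituent
    ranking), computes close-contact frequencies between candidate proton-donor
    residues and the substrate imine nitrogen, profiles hydrogen-bond frequency
    over donor-acceptor distance for a catalytic dyad, measures helix-rotation
    angles between binding modes via Kabsch superposition and principal-axis
    fitting, and enumerates polar protein-cofactor contact fingerprints. Includes
    a seeded synthetic-ensemble generator with per-frame ground truth for
    validating every statistic, plus multi-model PDB and XYZ input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
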