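Package: hemewire
Title: Geometry of Multiheme Cytochrome Nanowires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of heme packing in multiheme cytochromes and
    cytochrome filaments ("nanowires"). Reads PDB/mmCIF structures and
    extracts canonical 25-atom porphyrin rings; computes pairwise ring
    geometry (minimum edge-to-edge distance, rigid-body superposition and
    the rotation-angle statistic, packing-motif classes); builds heme
    contact graphs with main-chain tracing and branched-heme detection;
    measures per-heme solvent-accessible surface area (Shrake-Rupley) and
    subunit-interface buried area; performs helical-symmetry arithmetic
    (rise, twist, 1-start pitch, layer-line positions) and filament
    expansion; and generates synthetic structures with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
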