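Package: hygrolam
Title: Hygro-Elastic Laminate Analysis of Functionally Graded Seed Capsules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the humidity-driven opening of seed capsules whose walls
    are layered fiber/parenchyma composites with circumferentially graded
    layer thicknesses, as in sesame (Sesamum indicum). Implements classical
    laminate plate theory with hygroscopic load resultants to map a local
    layer stack to its free bending curvature, predicts normalized
    longitudinal curvature profiles around a locule circumference from
    relative layer-thickness profiles, and provides the accompanying
    measurement procedures: least-squares circle fitting of dried segment
    traces, relative circumferential positions from segment widths, wet/dry
    layer shrinkage, and cellulose microfibril-angle estimation from
    polarized-light azimuth/retardance maps with circular statistics.
    Includes seeded synthetic-data generators (graded thickness profiles,
    digitized arcs, azimuth maps, shrinkage tables) with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
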