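Package: ceprobe
Title: Normalization, Artifact Exclusion and Statistical Analysis of
    Capillary-Electrophoresis RNA Chemical Probing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes per-nucleotide peak-area tables from capillary
    electrophoresis (CE) readouts of RNA chemical probing experiments
    (SHAPE or DMS), as produced by ShapeFinder or QuShape. Automatically
    detects and excludes reverse-transcriptase strong-stop artifacts by a
    three-criterion background-ratio test, normalizes absolute
    reactivities onto the uniform SHAPE scale by capped box-plot
    normalization with a top-8% effective maximum, averages replicate
    profiles with per-nucleotide standard deviation, compares experiments
    through a Shapiro-Wilk / Bartlett / Mann-Whitney / Kruskal-Wallis
    cascade, renders reactivity and comparison plots, writes
    RNAstructure-compatible .shape restraint files, and bridges to an
    installed RNAstructure executable for data-driven secondary structure
    prediction. Includes a deterministic synthetic-data generator that
    plants strong-stops with guaranteed classification margins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
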