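Package: hicpileup
Title: Versatile Pile-Up (Aggregate) Analysis of Binned Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Averages many two-dimensional windows of sparse binned Hi-C
    contact matrices around annotated features (loop anchors, insulating
    boundaries, domains) to reveal average enrichment patterns invisible in
    sparse data. Reads single-resolution cooler-format (HDF5) contact
    matrices, BED region files and BEDPE region-pair files; supports
    off-diagonal, local, rescaled and anchored ("loop-ability") pile-up
    variants; normalizes by matrix balancing weights, per-bin coverage,
    chromosome-wide Toeplitz expected profiles, or randomly shifted control
    regions; and scores pile-ups by central enrichment with a corner
    coefficient-of-variation noise filter. Includes a synthetic contact-map
    generator with power-law distance decay, planted loops and domains,
    per-bin biases and Poisson sampling for fully reproducible validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    rhdf5,
    methods,
    parallel,
    stats,
    utils,
    tibble,
    dplyr,
    generics,
    rlang,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
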