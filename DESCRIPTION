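Package: lucifold
Title: Normalization, Fold Change and Visualization for Dual-Luciferase
    Reporter Assays
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Scriptable analysis of dual-luciferase reporter experiments
    run in 96-well plates. Parses plate-reader workbooks that store
    firefly and renilla luminescence as two 8x12 tables, merges per-well
    experimental designs, normalizes the firefly signal by the renilla
    internal control, computes fold change relative to a reference
    condition (globally or within strata), and produces summary tables
    and publication-grade dot plots that retain every individual data
    point. Includes a synthetic-experiment generator with a log-normal
    transfection-noise model for testing and power exploration, and a
    command-line interface for batch use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cellranger,
    dplyr,
    ggplot2,
    graphics,
    grDevices,
    jsonlite,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    zip
Suggests:
    png,
    ragg,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
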