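Package: pepfrac
Title: Quality Control and Visualisation for Peptide Isoelectric-Focussing Fractionation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses the quality of peptide-level isoelectric focussing
    (e.g. OFFGEL) fractionation experiments. Computes per-peptide
    physicochemistry (Henderson-Hasselbalch net-charge titration curves,
    isoelectric point, flat-charge-range focussing parameter, molecular
    weight, GRAVY hydropathy), quantifies how peptides span fractions
    (n-span categories, per-fraction unique percentages, adjacent-fraction
    overlaps), solves the area-proportional two-circle overlap geometry for
    a Venn-like chain diagram, and renders a one-page five-panel diagnostic
    figure. Includes a reproducible synthetic-data generator (tryptic
    digestion plus a pI-window carry-over model) and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    patchwork,
    generics,
    withr,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
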