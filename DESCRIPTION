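Package: bvquant
Title: Bacterial Viability Quantification and Substantivity Statistics for
    LIVE/DEAD Confocal Biofilm Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies bacterial viability in two-channel (SYTO 9 / propidium
    iodide) confocal z-stacks of saliva and dental-plaque biofilm samples:
    per-pixel live/dead classification on a 0-255 intensity scale, exclusion of
    epithelial cell nuclei by connected-component morphology (area, solidity,
    mean red intensity), minimum-area gating of optical sections, biofilm
    thickness and layer-resolved viability, and nonparametric crossover-trial
    substantivity statistics (paired and independent Wilcoxon tests with
    Bonferroni-adjusted significance levels). Includes ground-truthed synthetic
    generators for image stacks and trial tables so the full pipeline is
    testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
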