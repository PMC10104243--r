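Package: filarch
Title: Quantitative Filament-Architecture Analysis for Cryo-ET Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the three-dimensional architecture of cytoskeletal
    filament networks traced from cryo-electron tomograms of pancreatic
    beta-cells: filament orientation relative to the plasma membrane,
    pairwise distance and angle structure of the actin network (bundle
    detection), plasma-membrane anchoring and directed neighbor-angle
    analysis (netlike versus blooming architectures), and proximity of
    actin filaments and microtubules to insulin secretory granules.
    Also reimplements the 2D fluorescence meshwork skeleton metrics
    (total length and junction counts) and provides a synthetic scene
    generator with known ground truth for benchmarking every analysis
    stage. All record outputs are tidy tibbles suitable for piping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
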