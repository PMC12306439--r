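Package: microfission
Title: Lineage Tracking and Size-Control Analysis of Confined Algal Microcolonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-lapse segmentation tables of confined
    Chlamydomonas reinhardtii microcolonies growing under diurnal light-dark
    cycles. Reconstructs persistent cell identities and division events from
    per-frame feature tables (nearest-neighbour linking with size-drop
    division calls and frame-gap tolerance), detects colony-level division
    onsets from mean-size peak/valley structure, fits exponential growth
    rates and a multiple-fission mitotic sizer, estimates the commitment-size
    breakpoint by segmented regression of binned mitotic percentages, and
    computes spatially binned statistics (radial rings, kymographs) across
    the colony. Includes an agent-based synthetic microcolony generator with
    known ground truth for validating the tracker and the downstream
    statistics.
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
    jsonlite,
    mclust,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
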