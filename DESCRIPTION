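Package: piezoquant
Title: Quantification of PIEZO2 Mechanotransduction Assays
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for quantifying cellular
    mechanotransduction experiments on PIEZO2 channels and their
    intracellular-domain deletion mutants. Covers whole-cell poking-current
    analysis (leak subtraction, peak currents, mechanical activation
    threshold by a 6-SD onset rule, single-exponential inactivation fits,
    displacement-response curves, velocity-sensitivity ratios with
    stability QC, reversal potential), cell-attached pressure-clamp
    analysis (charge transfer, single-channel amplitude histograms with
    two-Gaussian fits, per-cell unitary conductance from I/V regression,
    responder calling, patch QC), TIRF cluster tracking (DoG spot
    detection, nearest-neighbour linking with gap closing, time-averaged
    MSD, four-way motility classification, 2D-Gaussian cluster diameters
    and densities), and the responder/neurite statistics (exact 2x2 tests,
    proportion summaries, normality-gated group comparisons). Every stage
    is driven by seeded synthetic-data generators that embed their ground
    truth, so the full pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    minpack.lm,
    jsonlite,
    tiff,
    EBImage,
    multcomp,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
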