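Package: ffaquant
Title: Quantitative Analysis of Rodent Fluorescein Fundus Angiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Standardized quantification of laser-induced choroidal
    neovascularization (CNV) from rodent fluorescein fundus angiogram (FFA)
    image sequences. Implements optic-nerve-head normalized lesion area,
    annulus-based local background estimation with vessel-free patch
    sampling, net fluorescence and area-corrected lesion intensity scores,
    fluorescein bolus kinetics (appearance and peak detection, gamma-variate
    and logarithmic-rise model fits for intravenous and intraperitoneal
    administration), choroidal flatmount area conversion, and group
    statistics with mean +/- SD summaries and two-tailed t-tests. Ships a
    synthetic fundus phantom generator with full ground truth so the entire
    pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    tiff,
    png,
    minpack.lm,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    mgcv
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
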