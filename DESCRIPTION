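Package: blisscreen
Title: Bliss-Based Linear Modeling of Sparse Drug-Combination Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Statistical analysis of large, dose-sparse drug-combination
    viability screens. Single-drug (singlet) log-viabilities are estimated
    by solving the over-determined linear system implied by Bliss
    independence over all pairwise-combination wells, borrowing strength
    across thousands of combinations instead of trusting single singlet
    wells. Residuals from the fit, calibrated against a DMSO-derived null
    variance, yield per-combination synergy and antagonism p values and
    Benjamini-Hochberg q values. Results are aggregated into drug-by-drug
    absolute and specificity synergy scores with permutation and
    binomial-marginal randomization nulls, plus plate preprocessing
    (one-iteration median polish of log counts, trimmed-mean DMSO
    normalization), a synthetic-screen generator, internal-consistency
    diagnostics, and a JSON export for heatmap visualization.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
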