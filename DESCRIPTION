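Package: arrestomix
Title: Chemometrics for Longitudinal Plasma Metabolomics in Experimental
    Cardiac Arrest
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools to analyse longitudinal plasma metabolomics from
    experimental models of asphyxial and dysrhythmic cardiac arrest:
    binning and normalisation of 1H NMR spectra, NIPALS principal
    component and PLS2 latent-variable models with post-transformation
    into predictive and orthogonal components (ptPLS2), cross-validated
    Q2 with permutation testing, VIP-based and Monte-Carlo stability
    variable selection, batch statistical process control charts of
    per-animal metabolic trajectories, and longitudinal mixed-effects and
    rank-based univariate statistics with false discovery rate control.
    Includes a synthetic swine-cohort generator with known ground truth
    for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
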