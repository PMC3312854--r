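Package: phtadjust
Title: Albumin-Adjusted Free Phenytoin Versus Measured Concentrations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates the Sheiner-Tozer albumin correction for phenytoin
    therapeutic drug monitoring against directly measured free phenytoin.
    Provides the adjustment and therapeutic-range classification, linkage of
    total/free phenytoin pairs to albumin results within a lookback window,
    three-by-three therapeutic-category concordance tables with Fisher and
    chi-squared comparisons, continuous method-agreement statistics (Pearson
    correlation, least-squares fits with identity-line tests, Bland-Altman
    limits of agreement, difference-versus-covariate regressions, ANOVA and
    t-tests), and a synthetic cohort generator that emulates the covariate
    structure of a large retrospective hospital population so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
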