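Package: cogmarker
Title: Digital Biomarkers of Depression from Online Attention Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless, testable pipeline for a sub-clinical digital
    depression-assessment battery built from three classic attention tasks:
    the d2 test of attention, delayed matching to sample (DMTS), and the
    CANTAB-style spatial working memory (SWM) search task. The package
    generates seeded task batteries, scores raw interaction event logs into
    fourteen behavioral measures, scores the PHQ-9 depression module,
    applies careless-responding filters (speed, zero-variance, and
    outlier-variance), and predicts PHQ-9 totals via hierarchical multiple
    regression with R-squared-change F tests, variance inflation factor
    diagnostics, and oblimin-rotated principal component analysis for
    combined-model metric selection. A generative participant simulator in
    which latent depression severity drives both questionnaire responses
    and task-error propensities closes the loop, so the whole pipeline is
    verifiable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
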