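Package: ushrv
Title: Ultra-Short-Term Heart Rate Variability Surrogate Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether ultra-short (below 5 minutes) heart rate
    variability (HRV) features are valid surrogates of standard 5-minute features
    for mental-stress detection. Provides annotated RR-interval input with an
    NN/RR signal-quality gate, central and consecutive window segmentation, a
    23-feature multiscale HRV extractor (time-domain, autoregressive spectral and
    non-linear features with per-scale computability masking), a statistical
    surrogate gate combining Wilcoxon trend coding, Spearman correlation
    screening and Bland-Altman agreement, a person-independent stress
    classification harness, and a synthetic paired rest/stress RR cohort
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
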