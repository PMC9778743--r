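Package: emovar
Title: Emotion Time Series and Preventive-Behavior Dynamics from Short Texts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for linking lexicon-scored discrete emotions (anger,
    anxiety, sadness) in timestamped short social-media texts to a 0-100
    preventive-behavior search index. Implements dictionary word-count
    emotion scoring with wildcard, phrase and emoticon entries, base-rate
    normalized daily and weekly emotion indices, weekly panel assembly
    against a Google-Trends-style behavior series, vector autoregression
    (VAR) estimation with AIC/BIC lag selection and companion-matrix
    stability diagnostics, Granger causality block F tests, and
    orthogonalized impulse-response functions with residual-bootstrap
    confidence bands. A synthetic-data module generates tweet-like corpora
    and coupled behavior series from a known ground-truth VAR so the whole
    pipeline can be validated end to end without any external data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
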