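Package: ipdinfer
Title: Inference on Predicted Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Statistically valid downstream inference when some or most
    outcome values are machine-generated predictions.  Implements the
    post-prediction inference (PostPI) analytic and bootstrap corrections,
    prediction-powered inference (PPI), power-tuned PPI (PPI++), and
    post-prediction adaptive inference (PSPA) for the population mean,
    quantile, linear regression, and logistic regression estimands,
    together with oracle, naive, and classic benchmark fits, sandwich
    variance estimation, a synthetic data generator for method evaluation,
    and broom-style print, summary, tidy, glance, and augment methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    mgcv,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
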