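Package: srmotion
Title: Stochastic Resonance in Motion Perception Across the Lifespan
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and inference pipeline for behavioural stochastic
    resonance in coherent-motion detection. Provides a random-dot
    kinematogram stimulus generator, a threshold stochastic-resonance
    observer whose internal noise can be tied to age, a one-up two-down
    adaptive staircase, an experiment runner with the standard exclusion
    rules, and the statistical analysis stage: a log-threshold linear
    model, binomial random-intercept generalized linear mixed models with
    orthogonal polynomial terms fitted by adaptive Gauss-Hermite
    quadrature, AICc model selection with Akaike weights, Type III Wald
    tests, Nakagawa marginal and part R-squared, accuracy-peak
    estimation, and simulation-based residual diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    glmmTMB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
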